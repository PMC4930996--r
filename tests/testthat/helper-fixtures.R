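# small in-code fixtures shared across test files

# samples table from a list of per-individual value vectors (one tissue,
# both isotopes equal unless given separately)
make_samples <- function(values, tissue = "red_blood_cell",
                         values13 = values, start_year = 2006) {
  dplyr::bind_rows(lapply(names(values), function(id) {
    v <- values[[id]]
    tibble::tibble(
      individual_id = id,
      year = seq(start_year, length.out = length(v)),
      tissue = tissue,
      d15N = v,
      d13C = values13[[id]]
    )
  }))
}

# minimal valid traits table covering the given samples
make_traits <- function(samples) {
  samples |>
    dplyr::distinct(individual_id, year) |>
    dplyr::mutate(
      body_mass = 2400 + seq_len(dplyr::n()),
      clutch_initiation_date = 30 + seq_len(dplyr::n()) %% 10,
      a_egg_mass = 80, b_egg_mass = 110
    )
}

# flat monthly env table with the given constant per (index, year, month)
make_env <- function(years, indices = "SAM", value = 0) {
  tidyr::expand_grid(index_name = indices, year = years, month = 1:12) |>
    dplyr::mutate(value = value)
}

# one-way layout: a groups x n reps with group effects sd_g, residual sd_e
make_one_way <- function(a, n, sd_g = 1, sd_e = 1, mu = 10) {
  g <- rep(seq_len(a), each = n)
  tibble::tibble(
    individual_id = sprintf("G%02d", g),
    y = mu + rnorm(a, 0, sd_g)[g] + rnorm(a * n, 0, sd_e)
  )
}

# small, fast synthetic config at the study design scale
quick_cfg <- function(...) synthetic_config(...)
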