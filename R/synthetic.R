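#' Default per-series generator parameters
#'
#' One row per tissue x isotope: the mean per-mil value and the three
#' variance components (among-individual, among-year, residual), plus the
#' environmental effect sizes (zero by default) and the index and random
#' slope SD used when an environmental link is switched on. The default
#' variances were chosen so the expected niche decomposition and
#' repeatability magnitudes resemble a multi-year seabird study: strong
#' among-individual structure in blood (prebreeding), weak in feathers
#' (premolt).
#'
#' @return a tibble with columns `tissue`, `isotope`, `mu`,
#'   `sigma2_individual`, `sigma2_year`, `sigma2_residual`,
#'   `beta_within`, `beta_between`, `slope_sd`, `env_index`.
#' @export
default_isotope_params <- function() {
  tibble::tribble(
    ~tissue,          ~isotope, ~mu,   ~sigma2_individual, ~sigma2_year, ~sigma2_residual,
    "red_blood_cell", "d15N",   12.9,  0.54,               0.30,         0.29,
    "red_blood_cell", "d13C",   -18.9, 0.09,               0.09,         0.10,
    "feather",        "d15N",   13.5,  0.15,               0.30,         0.23,
    "feather",        "d13C",   -17.6, 0.15,               0.20,         0.19
  ) |>
    dplyr::mutate(beta_within = 0, beta_between = 0, slope_sd = 0,
                  env_index = "SAM")
}

#' Configure the synthetic study generator
#'
#' Describes a multi-year individual-sampling design with crossed
#' individual and year effects. The defaults emulate the motivating study
#' design: 30 females followed over the 8-season span 2006-2013 with no
#' fieldwork in 2011 (7 sampled years), each blood-sampled in 3-6 years
#' (mean about 4.3, about 130 records), feathers collected in the same
#' years except 2009 (2-5 years per female, mean about 3.7). Environmental
#' indices are monthly AR(1) series; environmental and trait effect sizes
#' default to zero.
#'
#' @param n_individuals number of females.
#' @param study_years full span of seasons.
#' @param skip_years years inside the span with no fieldwork at all.
#' @param no_feather_years sampled years without feather collection.
#' @param blood_years_range min/max number of blood years per individual.
#' @param blood_years_probs sampling weights over
#'   `blood_years_range[1]:blood_years_range[2]` (defaults give mean 4.3).
#' @param max_feather_years cap on feather years per individual.
#' @param isotope_params per-series parameter tibble; see
#'   [default_isotope_params()]. Scalar overrides below, when non-`NULL`,
#'   replace the corresponding column in every row.
#' @param sigma2_individual,sigma2_year,sigma2_residual scalar overrides
#'   for the variance components (per-mil squared).
#' @param mu scalar override for the series means.
#' @param beta_within,beta_between scalar overrides for the environmental
#'   effect sizes (per permil per index unit).
#' @param slope_sd scalar override for the among-individual SD of the
#'   within-environment slope.
#' @param env_indices names of the monthly index series to generate.
#' @param env_sd,env_ar1 marginal SD and month-to-month AR(1) coefficient
#'   of each index (defaults give among-year window-mean SD near 1 index
#'   unit).
#' @param trait_link `list(beta_within =, beta_between =, isotope =)`:
#'   effect of the year-standardized blood isotope covariate on the
#'   breeding traits, on the standardized scale.
#' @param trait_variances z-scale variance components for the traits:
#'   `list(individual =, year =, residual =)`.
#' @param seed integer seed; the same config and seed give a
#'   byte-identical dataset.
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_individuals = 30,
                             study_years = 2006:2013,
                             skip_years = 2011L,
                             no_feather_years = 2009L,
                             blood_years_range = c(3L, 6L),
                             blood_years_probs = c(0.25, 0.35, 0.25, 0.15),
                             max_feather_years = 5L,
                             isotope_params = default_isotope_params(),
                             sigma2_individual = NULL,
                             sigma2_year = NULL,
                             sigma2_residual = NULL,
                             mu = NULL,
                             beta_within = NULL,
                             beta_between = NULL,
                             slope_sd = NULL,
                             env_indices = c("SAM", "SOI", "SSTA"),
                             env_sd = 1.2, env_ar1 = 0.3,
                             trait_link = list(beta_within = 0,
                                               beta_between = 0,
                                               isotope = "d15N"),
                             trait_variances = list(individual = 0.30,
                                                    year = 0.25,
                                                    residual = 0.45),
                             seed = 1L) {
  if (!all(skip_years %in% study_years)) {
    abort("skip_years must lie inside study_years")
  }
  sampled <- setdiff(study_years, skip_years)
  if (blood_years_range[2] > length(sampled)) {
    abort("infeasible design: more blood years requested than sampled years")
  }
  counts <- seq(blood_years_range[1], blood_years_range[2])
  if (length(blood_years_probs) != length(counts)) {
    abort("blood_years_probs must match blood_years_range")
  }
  for (col in c("sigma2_individual", "sigma2_year", "sigma2_residual",
                "mu", "beta_within", "beta_between", "slope_sd")) {
    v <- get(col)
    if (!is.null(v)) isotope_params[[col]] <- v
  }
  var_cols <- c("sigma2_individual", "sigma2_year", "sigma2_residual")
  if (any(as.matrix(isotope_params[var_cols]) < 0)) {
    abort("variance components must be non-negative")
  }
  structure(
    list(n_individuals = n_individuals,
         study_years = as.integer(study_years),
         skip_years = as.integer(skip_years),
         no_feather_years = as.integer(no_feather_years),
         sampled_years = as.integer(sampled),
         blood_years_range = as.integer(blood_years_range),
         blood_years_probs = blood_years_probs,
         max_feather_years = as.integer(max_feather_years),
         isotope_params = isotope_params,
         env_indices = env_indices, env_sd = env_sd, env_ar1 = env_ar1,
         trait_link = trait_link, trait_variances = trait_variances,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

## stationary monthly AR(1) series per index over the study span
generate_env_series <- function(cfg) {
  months <- tidyr::expand_grid(year = cfg$study_years, month = 1:12)
  purrr::map_dfr(cfg$env_indices, function(idx) {
    n <- nrow(months)
    innov_sd <- cfg$env_sd * sqrt(1 - cfg$env_ar1^2)
    v <- numeric(n)
    v[1] <- rnorm(1, 0, cfg$env_sd)
    for (t in 2:n) v[t] <- cfg$env_ar1 * v[t - 1] + rnorm(1, 0, innov_sd)
    tibble::tibble(index_name = idx, year = months$year,
                   month = months$month, value = v)
  })
}

#' Generate a synthetic multi-year isotope dataset
#'
#' Draws a full study dataset under the configured design: independent
#' Gaussian individual, year and residual effects per tissue x isotope
#' series; monthly AR(1) environmental index series; optional within- and
#' among-individual environmental effects (through the tissue's window
#' mean) and optional among-individual slope heterogeneity; breeding
#' traits for every blood year, linked to the standardized blood isotope
#' covariate on the z scale. All latent draws are returned so recovery
#' tests can compare estimates to truth.
#'
#' The isotope value of individual j in year i is
#' `mu + a_j + b_i + s_j (e_iy - ebar_j) + beta_w (e_iy - ebar_j)
#'  + beta_b ebar_j + eps_ij`,
#' with `a_j ~ N(0, sigma2_individual)`, `b_i ~ N(0, sigma2_year)`,
#' `s_j ~ N(0, slope_sd^2)`, `eps ~ N(0, sigma2_residual)`, and `e_iy`
#' the window mean of the linked index in year i (`ebar_j`: mean over
#' the individual's observed years).
#'
#' @param cfg a [synthetic_config()].
#' @return a list of class `iso_synthetic`: `dataset` (an
#'   [iso_dataset]), `truth` (latent effects and the realized design),
#'   and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_preserved_seed(cfg$seed, generate_dataset_impl(cfg))
}

generate_dataset_impl <- function(cfg) {
  ids <- sprintf("F%02d", seq_len(cfg$n_individuals))
  counts <- seq(cfg$blood_years_range[1], cfg$blood_years_range[2])

  ## realized sampling design
  design <- purrr::map(ids, function(id) {
    nb <- counts[sample.int(length(counts), 1,
                            prob = cfg$blood_years_probs)]
    blood <- sort(sample(cfg$sampled_years, nb))
    feather <- setdiff(blood, cfg$no_feather_years)
    if (length(feather) > cfg$max_feather_years) {
      feather <- sort(sample(feather, cfg$max_feather_years))
    }
    list(id = id, blood = blood, feather = feather)
  })

  env <- generate_env_series(cfg)

  ## latent effects + observed values per series
  truth_effects <- list()
  samples <- list()
  for (r in seq_len(nrow(cfg$isotope_params))) {
    pr <- cfg$isotope_params[r, ]
    key <- paste(pr$tissue, pr$isotope, sep = ".")
    a <- setNames(rnorm(length(ids), 0, sqrt(pr$sigma2_individual)), ids)
    b <- setNames(rnorm(length(cfg$sampled_years), 0, sqrt(pr$sigma2_year)),
                  as.character(cfg$sampled_years))
    s <- setNames(rnorm(length(ids), 0, pr$slope_sd), ids)
    win <- default_env_window(pr$tissue)
    ewin <- setNames(
      env_window_mean(env, pr$env_index, cfg$sampled_years, win),
      as.character(cfg$sampled_years)
    )
    rows <- purrr::map_dfr(design, function(d) {
      yrs <- if (pr$tissue == "red_blood_cell") d$blood else d$feather
      if (length(yrs) == 0) return(NULL)
      e <- ewin[as.character(yrs)]
      ebar <- mean(e)
      tibble::tibble(
        individual_id = d$id, year = yrs, tissue = pr$tissue,
        isotope = pr$isotope,
        value = pr$mu + a[d$id] + b[as.character(yrs)] +
          (pr$beta_within + s[d$id]) * (e - ebar) +
          pr$beta_between * ebar +
          rnorm(length(yrs), 0, sqrt(pr$sigma2_residual))
      )
    })
    samples[[key]] <- rows
    truth_effects[[key]] <- list(individual = a, year = b, slope = s,
                                 params = as.list(pr))
  }
  samples <- dplyr::bind_rows(samples) |>
    tidyr::pivot_wider(names_from = "isotope", values_from = "value") |>
    dplyr::arrange(.data$tissue, .data$individual_id, .data$year)

  traits <- generate_traits(cfg, samples, ids)

  ds <- iso_dataset(samples, traits$table, env,
                    study_years = cfg$sampled_years)
  structure(
    list(dataset = ds,
         truth = list(effects = truth_effects,
                      trait_effects = traits$truth,
                      design = design),
         config = cfg),
    class = "iso_synthetic"
  )
}

## traits on the z scale, linked to the year-standardized blood isotope,
## then mapped to natural units; total clutch mass = A-egg + B-egg exactly
generate_traits <- function(cfg, samples, ids) {
  link <- cfg$trait_link
  tv <- cfg$trait_variances
  blood <- samples |>
    dplyr::filter(.data$tissue == "red_blood_cell") |>
    dplyr::select(dplyr::all_of(c("individual_id", "year",
                                  link$isotope)))
  if (link$beta_within == 0 && link$beta_between == 0) {
    # covariate unused; skip standardization (which is undefined when an
    # isotope series is degenerate, e.g. all-zero-variance configs)
    cov_frame <- blood
    w <- btw <- numeric(nrow(blood))
  } else {
    cov_frame <- blood |>
      standardize_within_year(link$isotope) |>
      center_within_individual(link$isotope)
    w <- cov_frame[[paste0(link$isotope, "_within")]]
    btw <- cov_frame[[paste0(link$isotope, "_between")]]
  }
  n <- nrow(cov_frame)
  scales <- list(
    body_mass = c(mean = 2450, sd = 250),
    clutch_initiation_date = c(mean = 35, sd = 4),
    total_clutch_mass = c(mean = 190, sd = 15)
  )
  truth <- list()
  out <- cov_frame[c("individual_id", "year")]
  for (tr in names(scales)) {
    u <- setNames(rnorm(length(ids), 0, sqrt(tv$individual)), ids)
    v <- setNames(
      rnorm(length(cfg$sampled_years), 0, sqrt(tv$year)),
      as.character(cfg$sampled_years)
    )
    z <- link$beta_within * w + link$beta_between * btw +
      u[out$individual_id] + v[as.character(out$year)] +
      rnorm(n, 0, sqrt(tv$residual))
    out[[tr]] <- scales[[tr]][["mean"]] + scales[[tr]][["sd"]] * z
    truth[[tr]] <- list(individual = u, year = v)
  }
  out$clutch_initiation_date <- round(out$clutch_initiation_date)
  a_share <- 0.42 + rnorm(n, 0, 0.01)
  out$a_egg_mass <- out$total_clutch_mass * a_share
  out$b_egg_mass <- out$total_clutch_mass - out$a_egg_mass
  out$total_clutch_mass <- NULL
  list(table = out, truth = truth)
}

#' Generate a dataset with no individual structure or covariate effects
#'
#' Convenience wrapper for null (type-I-error) simulations: the config's
#' among-individual variances, environmental effect sizes, slope SDs and
#' trait links are all forced to zero before generating.
#'
#' @param cfg a [synthetic_config()].
#' @return an `iso_synthetic` list, as [generate_dataset()].
#' @export
generate_null_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cfg$isotope_params$sigma2_individual <- 0
  cfg$isotope_params$beta_within <- 0
  cfg$isotope_params$beta_between <- 0
  cfg$isotope_params$slope_sd <- 0
  cfg$trait_link$beta_within <- 0
  cfg$trait_link$beta_between <- 0
  cfg$trait_variances$individual <- 0
  generate_dataset(cfg)
}

#' Write a synthetic dataset and its ground truth to disk
#'
#' Writes the three analysis CSVs (via [write_iso_dataset()]) plus a
#' `truth.json` with every latent effect, for external recovery checks.
#'
#' @param x an `iso_synthetic` object.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_synthetic <- function(x, dir) {
  stopifnot(inherits(x, "iso_synthetic"))
  write_iso_dataset(x$dataset, dir)
  truth <- x$truth
  truth$design <- purrr::map(truth$design, function(d) {
    list(id = d$id, blood = d$blood, feather = d$feather)
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
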