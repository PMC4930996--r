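#' Split a covariate into within- and among-individual parts
#'
#' Within-subject centering: for covariate x of individual j in year i,
#' the among-individual part is the individual's mean over its observed
#' years only (x_bar_j), and the within-individual part is the deviation
#' x_ij - x_bar_j. Including both as separate fixed effects lets a mixed
#' model separate phenotypic plasticity (within) from consistent
#' among-individual differences (between). Individuals observed once get a
#' within value of 0.
#'
#' @param data a data frame.
#' @param col name of the covariate column.
#' @param id name of the individual identifier column.
#' @return `data` with two added columns `<col>_within` and
#'   `<col>_between`. Within values sum to zero inside each individual and
#'   `within + between` reconstructs the covariate exactly.
#' @examples
#' df <- tibble::tibble(individual_id = c("a", "a", "a"), x = c(2, 4, 6))
#' center_within_individual(df, "x")
#' @export
center_within_individual <- function(data, col, id = "individual_id") {
  data <- tibble::as_tibble(data)
  if (!col %in% names(data)) abort(sprintf("column '%s' not found", col))
  data |>
    dplyr::mutate(
      "{col}_between" := mean(.data[[col]]),
      "{col}_within" := .data[[col]] - mean(.data[[col]]),
      .by = dplyr::all_of(id)
    )
}

#' Standardize values within each year
#'
#' Replaces each value by its z-score within its year stratum (mean 0,
#' sample SD 1 per year), removing among-year level differences before
#' cross-year modelling. A year with fewer than two distinct values has no
#' defined z-score and raises an error naming the year.
#'
#' @param data a data frame with a year column.
#' @param cols character vector of numeric columns to standardize (in
#'   place).
#' @param year name of the year column.
#' @return `data` with the named columns standardized within year.
#' @export
standardize_within_year <- function(data, cols, year = "year") {
  data <- tibble::as_tibble(data)
  for (col in cols) {
    bad <- data |>
      dplyr::summarise(
        s = stats::sd(.data[[col]], na.rm = TRUE),
        .by = dplyr::all_of(year)
      ) |>
      dplyr::filter(is.na(.data$s) | .data$s < 1e-12)
    if (nrow(bad) > 0) {
      abort(sprintf(
        "cannot z-standardize '%s': constant or singleton stratum in year(s) %s",
        col, paste(bad[[year]], collapse = ", ")
      ), class = "iso_constant_stratum")
    }
    data <- data |>
      dplyr::mutate(
        "{col}" := (.data[[col]] - mean(.data[[col]], na.rm = TRUE)) /
          stats::sd(.data[[col]], na.rm = TRUE),
        .by = dplyr::all_of(year)
      )
  }
  data
}

#' Average an environmental index over a monthly window
#'
#' The year-level environmental covariates are two-month window means of a
#' monthly index series: August-September of the sampling year for the
#' prebreeding (red-blood-cell) period, February-March for the premolt
#' (feather) period. No cross-year wrapping: the window months are taken
#' from the stated calendar year.
#'
#' @param env monthly series table (`index_name`, `year`, `month`,
#'   `value`) — an [iso_dataset]`$env` or equivalent.
#' @param index_name which index (e.g. `"SAM"`).
#' @param years integer vector of years.
#' @param months integer vector of months to average (e.g. `c(8, 9)`).
#' @return numeric vector of window means, one per element of `years`.
#' @export
env_window_mean <- function(env, index_name, years, months) {
  if (inherits(env, "iso_dataset")) env <- env$env
  sub <- dplyr::filter(env, .data$index_name == !!index_name)
  vapply(years, function(y) {
    v <- sub$value[sub$year == y & sub$month %in% months]
    if (length(v) != length(months)) {
      miss <- setdiff(months, sub$month[sub$year == y])
      abort(sprintf("missing env value(s): %s year %d month(s) %s",
                    index_name, y, paste(miss, collapse = ", ")),
            class = "iso_missing_env")
    }
    mean(v)
  }, numeric(1))
}

#' Pairwise correlations between environmental window means
#'
#' The collinearity report behind the one-variable-per-model rule: window
#' means of different indices can be strongly correlated across the few
#' study years, so candidate environmental variables are fitted in
#' separate models rather than jointly.
#'
#' @param env monthly series table or [iso_dataset].
#' @param years years over which to correlate.
#' @param months window months.
#' @return tibble with one row per index pair: `index_a`, `index_b`, `r`,
#'   `p_value`, `n_years`.
#' @export
env_window_correlations <- function(env, years, months) {
  if (inherits(env, "iso_dataset")) env <- env$env
  idx <- sort(unique(env$index_name))
  if (length(idx) < 2) {
    return(tibble::tibble(index_a = character(), index_b = character(),
                          r = double(), p_value = double(),
                          n_years = integer()))
  }
  pairs <- utils::combn(idx, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- env_window_mean(env, pr[1], years, months)
    b <- env_window_mean(env, pr[2], years, months)
    ct <- stats::cor.test(a, b, method = "pearson")
    tibble::tibble(index_a = pr[1], index_b = pr[2],
                   r = unname(ct$estimate), p_value = ct$p.value,
                   n_years = length(years))
  })
}

#' Correlation of isotope values between tissues
#'
#' Pearson correlation between red-blood-cell and feather values of one
#' isotope, over (individual, year) pairs measured in both tissues. Tests
#' whether prebreeding and premolt foraging are linked within birds.
#'
#' @param ds an [iso_dataset].
#' @param isotope `"d15N"` or `"d13C"`.
#' @return a one-row tibble: `isotope`, `r`, `p_value`, `n_pairs`.
#' @export
tissue_correlation <- function(ds, isotope) {
  isotope <- match.arg(isotope, isotope_levels())
  wide <- ds$samples |>
    dplyr::select(dplyr::all_of(c("individual_id", "year", "tissue",
                                  isotope))) |>
    tidyr::pivot_wider(names_from = "tissue",
                       values_from = dplyr::all_of(isotope)) |>
    dplyr::filter(!is.na(.data$red_blood_cell), !is.na(.data$feather))
  if (nrow(wide) < 3) {
    abort("tissue correlation needs >= 3 matched (individual, year) pairs",
          class = "iso_too_few_pairs")
  }
  ct <- stats::cor.test(wide$red_blood_cell, wide$feather,
                        method = "pearson")
  tibble::tibble(isotope = isotope, r = unname(ct$estimate),
                 p_value = ct$p.value, n_pairs = nrow(wide))
}
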