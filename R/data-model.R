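#' Assemble a validated isotope study dataset
#'
#' Bundles the three long-format tables the analysis consumes — repeated
#' tissue isotope samples, per-(female, year) breeding traits, and monthly
#' environmental index series — into a single validated object. All
#' downstream stages (niche decomposition, repeatability, mixed-model sets)
#' take this object.
#'
#' @param samples data frame with columns `individual_id`, `year`,
#'   `tissue` (one of `"red_blood_cell"`, `"feather"`), `d15N`, `d13C`
#'   (per-mil values).
#' @param traits data frame with columns `individual_id`, `year`,
#'   `body_mass` (g), `clutch_initiation_date` (day of season, 1 = 1 October),
#'   `a_egg_mass` (g), `b_egg_mass` (g). A `total_clutch_mass` column is
#'   derived as the sum of the two egg masses; if present it must equal that
#'   sum. May be `NULL` when only the isotope stages are needed.
#' @param env data frame with columns `index_name` (e.g. `"SAM"`, `"SOI"`,
#'   `"SSTA"`), `year`, `month` (1-12), `value`. May be `NULL`.
#' @param study_years integer vector of years fieldwork took place. Samples
#'   from other years trigger a warning but are retained, so the tool
#'   generalizes beyond any one study design.
#' @return An object of class `iso_dataset`: a list with tibbles `samples`,
#'   `traits`, `env` and the `study_years` vector.
#' @examples
#' s <- tibble::tibble(
#'   individual_id = c("F01", "F01", "F02"), year = c(2006, 2007, 2006),
#'   tissue = "red_blood_cell", d15N = c(12.8, 13.1, 12.2),
#'   d13C = c(-18.9, -18.7, -19.2)
#' )
#' iso_dataset(s, study_years = 2006:2007)
#' @export
iso_dataset <- function(samples, traits = NULL, env = NULL,
                        study_years = NULL) {
  samples <- validate_samples(samples, study_years)
  traits <- if (!is.null(traits)) validate_traits(traits) else empty_traits()
  env <- if (!is.null(env)) validate_env(env) else empty_env()
  structure(
    list(
      samples = samples,
      traits = traits,
      env = env,
      study_years = as.integer(study_years %||% sort(unique(samples$year)))
    ),
    class = "iso_dataset"
  )
}

#' @export
print.iso_dataset <- function(x, ...) {
  cat(sprintf(
    "<iso_dataset> %d isotope samples (%d individuals, years %s)\n",
    nrow(x$samples), dplyr::n_distinct(x$samples$individual_id),
    paste(range(x$samples$year), collapse = "-")
  ))
  tab <- dplyr::count(x$samples, .data$tissue)
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %s: %d records\n", tab$tissue[i], tab$n[i]))
  }
  cat(sprintf(
    "  traits: %d rows; env: %d monthly values (%s)\n",
    nrow(x$traits), nrow(x$env),
    paste(unique(x$env$index_name), collapse = ", ")
  ))
  invisible(x)
}

tissue_levels <- function() c("red_blood_cell", "feather")
isotope_levels <- function() c("d15N", "d13C")

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "iso_schema_error")
  }
}

validate_samples <- function(samples, study_years = NULL) {
  require_columns(
    samples, c("individual_id", "year", "tissue", "d15N", "d13C"),
    "samples table"
  )
  samples <- tibble::as_tibble(samples)
  samples$individual_id <- as.character(samples$individual_id)
  samples$year <- as.integer(samples$year)

  bad_tissue <- setdiff(unique(samples$tissue), tissue_levels())
  if (length(bad_tissue) > 0) {
    abort(sprintf(
      "unknown tissue value(s): %s (expected %s)",
      paste(bad_tissue, collapse = ", "),
      paste(tissue_levels(), collapse = ", ")
    ), class = "iso_schema_error")
  }
  for (col in isotope_levels()) {
    bad <- which(!is.finite(samples[[col]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "non-finite %s value(s) in samples row(s) %s",
        col, paste(head(bad, 5), collapse = ", ")
      ), class = "iso_parse_error")
    }
  }
  dup <- samples |>
    dplyr::count(.data$individual_id, .data$year, .data$tissue) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate (individual, year, tissue) key(s): %s",
      paste(sprintf("(%s, %d, %s)", dup$individual_id, dup$year, dup$tissue),
            collapse = "; ")
    ), class = "iso_integrity_error")
  }
  if (!is.null(study_years)) {
    off <- sort(unique(samples$year[!samples$year %in% study_years]))
    if (length(off) > 0) {
      warn(sprintf(
        "samples from year(s) outside the declared study years: %s (rows retained)",
        paste(off, collapse = ", ")
      ), class = "iso_year_warning")
    }
  }
  samples
}

validate_traits <- function(traits) {
  require_columns(
    traits,
    c("individual_id", "year", "body_mass", "clutch_initiation_date",
      "a_egg_mass", "b_egg_mass"),
    "traits table"
  )
  traits <- tibble::as_tibble(traits)
  traits$individual_id <- as.character(traits$individual_id)
  traits$year <- as.integer(traits$year)
  mass_cols <- c("body_mass", "a_egg_mass", "b_egg_mass")
  for (col in mass_cols) {
    bad <- which(!is.na(traits[[col]]) & traits[[col]] <= 0)
    if (length(bad) > 0) {
      abort(sprintf("non-positive %s in traits row(s) %s",
                    col, paste(head(bad, 5), collapse = ", ")),
            class = "iso_integrity_error")
    }
  }
  derived <- traits$a_egg_mass + traits$b_egg_mass
  if ("total_clutch_mass" %in% names(traits)) {
    ok <- is.na(traits$total_clutch_mass) | is.na(derived) |
      abs(traits$total_clutch_mass - derived) < 1e-8
    if (!all(ok)) {
      abort("total_clutch_mass does not equal a_egg_mass + b_egg_mass",
            class = "iso_integrity_error")
    }
    traits$total_clutch_mass <- derived
  } else {
    traits$total_clutch_mass <- derived
  }
  dup <- traits |>
    dplyr::count(.data$individual_id, .data$year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate (individual, year) key(s) in traits: %s",
      paste(sprintf("(%s, %d)", dup$individual_id, dup$year), collapse = "; ")
    ), class = "iso_integrity_error")
  }
  traits
}

validate_env <- function(env) {
  require_columns(env, c("index_name", "year", "month", "value"), "env table")
  env <- tibble::as_tibble(env)
  env$index_name <- as.character(env$index_name)
  env$year <- as.integer(env$year)
  env$month <- as.integer(env$month)
  if (any(env$month < 1 | env$month > 12)) {
    abort("env months must lie in 1..12", class = "iso_schema_error")
  }
  dup <- env |>
    dplyr::count(.data$index_name, .data$year, .data$month) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate (index, year, month) key(s) in env: %s",
      paste(sprintf("(%s, %d, %d)", dup$index_name, dup$year, dup$month),
            collapse = "; ")
    ), class = "iso_integrity_error")
  }
  env
}

empty_traits <- function() {
  tibble::tibble(
    individual_id = character(), year = integer(), body_mass = double(),
    clutch_initiation_date = double(), a_egg_mass = double(),
    b_egg_mass = double(), total_clutch_mass = double()
  )
}

empty_env <- function() {
  tibble::tibble(
    index_name = character(), year = integer(), month = integer(),
    value = double()
  )
}

#' Read an isotope study dataset from CSV files
#'
#' Reads the three standard CSV tables (RFC-4180, UTF-8, "." decimal) and
#' returns a validated [iso_dataset]. Malformed files fail with errors that
#' name the offending column or key.
#'
#' @param samples_path path to `samples.csv`
#'   (`individual_id,year,tissue,d15N,d13C`).
#' @param traits_path optional path to `traits.csv`
#'   (`individual_id,year,body_mass,clutch_initiation_date,a_egg_mass,b_egg_mass`).
#' @param env_path optional path to `env.csv` (`index_name,year,month,value`).
#' @param study_years optional integer vector of expected fieldwork years;
#'   out-of-design years warn but are kept.
#' @return an [iso_dataset].
#' @export
read_iso_dataset <- function(samples_path, traits_path = NULL,
                             env_path = NULL, study_years = NULL) {
  samples <- readr::read_csv(samples_path, show_col_types = FALSE,
                             progress = FALSE)
  traits <- if (!is.null(traits_path)) {
    readr::read_csv(traits_path, show_col_types = FALSE, progress = FALSE)
  }
  env <- if (!is.null(env_path)) {
    readr::read_csv(env_path, show_col_types = FALSE, progress = FALSE)
  }
  iso_dataset(samples, traits, env, study_years = study_years)
}

#' Write an isotope study dataset to CSV files
#'
#' Inverse of [read_iso_dataset()]: writes `samples.csv`, `traits.csv` and
#' `env.csv` into a directory. Reading them back reproduces the dataset
#' (identifiers exactly, reals to full double precision).
#'
#' @param ds an [iso_dataset].
#' @param dir output directory (created if absent).
#' @return the paths of the written files, invisibly.
#' @export
write_iso_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "iso_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    samples = file.path(dir, "samples.csv"),
    traits = file.path(dir, "traits.csv"),
    env = file.path(dir, "env.csv")
  )
  readr::write_csv(ds$samples, paths[["samples"]])
  readr::write_csv(ds$traits, paths[["traits"]])
  readr::write_csv(ds$env, paths[["env"]])
  invisible(paths)
}

#' Restrict a dataset to individuals with enough years of data
#'
#' Keeps only individuals that have (a) at least `min_blood_years` years
#' with a red-blood-cell sample and complete values for every trait in
#' `required_traits` in that same year, and (b) at least `min_feather_years`
#' years with a feather sample. Retained individuals keep all of their
#' records, including ones in years that did not count toward the
#' thresholds. The operation is idempotent.
#'
#' @param ds an [iso_dataset].
#' @param min_blood_years minimum number of qualifying blood years
#'   (default 3, the study's inclusion rule).
#' @param min_feather_years minimum number of feather years (default 2).
#' @param required_traits trait columns that must be non-missing in a year
#'   for that year to count as a blood year. Use `character()` to require
#'   isotopes only.
#' @return the filtered [iso_dataset].
#' @export
filter_minimum_years <- function(ds, min_blood_years = 3,
                                 min_feather_years = 2,
                                 required_traits = c("body_mass",
                                                     "a_egg_mass",
                                                     "b_egg_mass")) {
  stopifnot(inherits(ds, "iso_dataset"))
  if (min_blood_years < 1 || min_feather_years < 1) {
    abort("minimum-year thresholds must be >= 1")
  }
  blood <- dplyr::filter(ds$samples, .data$tissue == "red_blood_cell")
  if (length(required_traits) > 0) {
    require_columns(ds$traits, required_traits, "traits table")
    complete <- ds$traits[
      stats::complete.cases(ds$traits[required_traits]),
      c("individual_id", "year")
    ]
    blood <- dplyr::semi_join(blood, complete,
                              by = c("individual_id", "year"))
  }
  blood_n <- blood |>
    dplyr::distinct(.data$individual_id, .data$year) |>
    dplyr::count(.data$individual_id, name = "n_blood")
  feather_n <- ds$samples |>
    dplyr::filter(.data$tissue == "feather") |>
    dplyr::distinct(.data$individual_id, .data$year) |>
    dplyr::count(.data$individual_id, name = "n_feather")
  keep <- dplyr::full_join(blood_n, feather_n, by = "individual_id") |>
    tidyr::replace_na(list(n_blood = 0L, n_feather = 0L)) |>
    dplyr::filter(.data$n_blood >= min_blood_years,
                  .data$n_feather >= min_feather_years) |>
    dplyr::pull(.data$individual_id)
  if (length(keep) == 0) {
    abort("no individual meets the minimum-year thresholds",
          class = "iso_empty_dataset")
  }
  out <- ds
  out$samples <- dplyr::filter(ds$samples, .data$individual_id %in% keep)
  out$traits <- dplyr::filter(ds$traits, .data$individual_id %in% keep)
  out
}
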