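#' Default analysis configuration
#'
#' The full-pipeline settings: inclusion thresholds (blood plus complete
#' traits in at least 3 years, feathers in at least 2), the variance
#' convention of the niche decomposition, bootstrap size for
#' repeatability standard errors, the significance gate for the
#' random-slope stage, whether quadratic environmental models are
#' included, and the window months per tissue.
#'
#' @param ... named overrides of the defaults.
#' @return a named list.
#' @export
default_analysis_config <- function(...) {
  cfg <- list(
    min_blood_years = 3,
    min_feather_years = 2,
    required_traits = c("body_mass", "a_egg_mass", "b_egg_mass"),
    convention = "population",
    n_boot = 1000,
    alpha_gate = 0.05,
    quadratic = TRUE,
    env_window = list(red_blood_cell = c(8, 9), feather = c(2, 3)),
    traits = c("body_mass", "clutch_initiation_date",
               "total_clutch_mass"),
    seed = 1L
  )
  utils::modifyList(cfg, list(...))
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file; keys override [default_analysis_config()]. A
#'   `synthetic:` block, if present, is passed to [synthetic_config()].
#' @return a named list.
#' @export
read_analysis_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_analysis_config(), user)
  cfg
}

run_stage <- function(stage, report, code) {
  inform(sprintf("[%s] ...", stage), class = "iso_stage_message")
  tryCatch(code, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "iso_stage_error",
          partial_report = report)
  })
}

#' Run the full multi-year specialization analysis
#'
#' Sequences every stage on a dataset: minimum-year filtering, niche
#' decomposition (TNW/WIC/AIC and WIC/TNW per tissue x isotope),
#' among-year repeatability of each series, the environmental
#' model-comparison sets for all four isotope responses (null, linear and
#' quadratic models per index) with the within-effect/random-slope gate,
#' the isotope-to-breeding-trait model sets, between-tissue isotope
#' correlations, and the environmental collinearity report. With the
#' default three indices and quadratic models on, the environmental stage
#' comprises 28 models (4 responses x (1 null + 3 indices x 2 forms)) and
#' the trait stage 9 models (3 traits x (1 null + 2 isotope covariates)).
#'
#' @param ds an [iso_dataset], or `NULL` to analyze a synthetic dataset
#'   generated from `synthetic`.
#' @param config a list from [default_analysis_config()] or
#'   [read_analysis_config()].
#' @param synthetic optional [synthetic_config()] used when `ds` is
#'   `NULL`.
#' @return an object of class `iso_analysis_report`: `niche`,
#'   `repeatability`, `env_models` (one comparison table per response),
#'   `env_gates`, `trait_models`, `tissue_correlations`,
#'   `env_correlations`, and `provenance`.
#' @examples
#' \donttest{
#' rep <- run_full_analysis(synthetic = synthetic_config(seed = 42),
#'                          config = default_analysis_config(n_boot = 50))
#' rep$niche
#' }
#' @export
run_full_analysis <- function(ds = NULL, config = default_analysis_config(),
                              synthetic = NULL) {
  report <- list()
  if (is.null(ds)) {
    if (is.null(synthetic)) synthetic <- synthetic_config(seed = config$seed)
    ds <- run_stage("simulate", report, generate_dataset(synthetic)$dataset)
  }
  report$provenance <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("isoniche")),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  ds <- run_stage("filter", report, filter_minimum_years(
    ds, config$min_blood_years, config$min_feather_years,
    config$required_traits
  ))

  report$niche <- run_stage("niche_decomposition", report,
                            niche_decomposition(ds,
                                                convention =
                                                  config$convention))

  report$repeatability <- run_stage("repeatability", report, {
    grid <- tidyr::expand_grid(tissue = tissue_levels(),
                               isotope = isotope_levels())
    purrr::pmap_dfr(grid, function(tissue, isotope) {
      x <- tissue_samples(ds, tissue, isotope)
      names(x)[names(x) == "value"] <- isotope
      res <- repeatability(x, isotope, "individual_id",
                           n_boot = config$n_boot, seed = config$seed)
      dplyr::bind_cols(tibble::tibble(tissue = tissue, isotope = isotope),
                       res)
    })
  })

  report$env_correlations <- run_stage("env_correlations", report, {
    purrr::map_dfr(tissue_levels(), function(t) {
      yrs <- sort(unique(ds$samples$year[ds$samples$tissue == t]))
      env_window_correlations(ds$env, yrs, config$env_window[[t]]) |>
        dplyr::mutate(tissue = t, .before = 1)
    })
  })

  env_stage <- run_stage("env_models", report, {
    grid <- tidyr::expand_grid(tissue = tissue_levels(),
                               isotope = isotope_levels())
    tables <- purrr::pmap(grid, function(tissue, isotope) {
      build_environment_model_set(
        ds, tissue, isotope,
        months = config$env_window[[tissue]],
        quadratic = config$quadratic
      )
    })
    names(tables) <- paste(grid$tissue, grid$isotope, sep = ".")
    gates <- purrr::pmap_dfr(grid, function(tissue, isotope) {
      tab <- tables[[paste(tissue, isotope, sep = ".")]]
      best <- best_env_model(tab)
      if (is.na(best$index)) {
        return(tibble::tibble(tissue = tissue, isotope = isotope,
                              best_model = best$label,
                              p_within = NA_real_,
                              within_significant = NA,
                              slope_evaluated = FALSE))
      }
      frame <- prepare_env_model_frame(ds, tissue, isotope,
                                       months =
                                         config$env_window[[tissue]])
      extra <- if (best$quadratic) {
        paste0(best$index, c("_within2", "_between2"))
      } else {
        character()
      }
      gate <- test_within_effect_then_slopes(
        frame, isotope,
        within = paste0(best$index, "_within"),
        between = paste0(best$index, "_between"),
        extra_fixed = extra, alpha = config$alpha_gate
      )
      dplyr::bind_cols(tibble::tibble(tissue = tissue, isotope = isotope,
                                      best_model = best$label), gate)
    })
    list(tables = tables, gates = gates)
  })
  report$env_models <- env_stage$tables
  report$env_gates <- env_stage$gates

  report$trait_models <- run_stage("trait_models", report, {
    tables <- purrr::map(config$traits, function(tr) {
      build_trait_model_set(ds, tr, alpha = config$alpha_gate)
    })
    names(tables) <- config$traits
    tables
  })

  report$tissue_correlations <- run_stage("tissue_correlations", report, {
    purrr::map_dfr(isotope_levels(), function(iso) {
      tissue_correlation(ds, iso)
    })
  })

  structure(report, class = "iso_analysis_report")
}

## best non-null environmental model in a comparison table (by AIC);
## falls back to the null row when nothing beats it or fits failed
best_env_model <- function(tab) {
  nonnull <- tab[tab$model != "Null" & !is.na(tab$akaike_ic), ]
  if (nrow(nonnull) == 0) {
    return(list(label = "Null", index = NA_character_, quadratic = FALSE))
  }
  top <- nonnull[which.min(nonnull$akaike_ic), ]
  list(label = top$model,
       index = sub(" .*", "", top$model),
       quadratic = grepl("\\^2", top$model))
}

#' @export
print.iso_analysis_report <- function(x, ...) {
  cat("<iso_analysis_report>\n")
  cat(sprintf("  niche decomposition: %d series\n", nrow(x$niche)))
  cat(sprintf("  repeatability: %d series\n", nrow(x$repeatability)))
  cat(sprintf("  environmental models: %d\n",
              sum(vapply(x$env_models, nrow, integer(1)))))
  cat(sprintf("  trait models: %d\n",
              sum(vapply(x$trait_models, nrow, integer(1)))))
  cat(sprintf("  seed %s, config %s\n", x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8)))
  invisible(x)
}

#' Count the models in a report's comparison stages
#'
#' @param report an `iso_analysis_report`.
#' @return tibble with `n_env_models` and `n_trait_models` (both include
#'   the null models).
#' @export
report_model_counts <- function(report) {
  tibble::tibble(
    n_env_models = sum(vapply(report$env_models, nrow, integer(1))),
    n_trait_models = sum(vapply(report$trait_models, nrow, integer(1)))
  )
}

#' Write an analysis report to a directory
#'
#' TSV tables (niche decomposition, repeatability, every model-comparison
#' table) plus a single structured `report.json` with everything
#' including provenance.
#'
#' @param report an `iso_analysis_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  stopifnot(inherits(report, "iso_analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_niche_table(report$niche, file.path(dir, "niche.tsv"))
  readr::write_tsv(report$repeatability,
                   file.path(dir, "repeatability.tsv"))
  for (nm in names(report$env_models)) {
    write_comparison_table(report$env_models[[nm]],
                           file.path(dir, sprintf("env_models_%s.tsv", nm)))
  }
  for (nm in names(report$trait_models)) {
    write_comparison_table(
      report$trait_models[[nm]],
      file.path(dir, sprintf("trait_models_%s.tsv", nm))
    )
  }
  json <- list(
    provenance = report$provenance,
    niche = report$niche,
    repeatability = report$repeatability,
    env_models = purrr::map(report$env_models, strip_attrs),
    env_gates = report$env_gates,
    trait_models = purrr::map(report$trait_models, strip_attrs),
    tissue_correlations = report$tissue_correlations,
    env_correlations = report$env_correlations
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

strip_attrs <- function(tab) {
  attr(tab, "fits") <- NULL
  attr(tab, "effect_tests") <- NULL
  class(tab) <- c("tbl_df", "tbl", "data.frame")
  tab
}
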