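#' Default environmental window months per tissue
#'
#' Red blood cells integrate the prebreeding period (August-September of
#' the sampling year); feathers integrate the premolt period
#' (February-March of the molt year).
#'
#' @param tissue `"red_blood_cell"` or `"feather"`.
#' @return integer vector of months.
#' @export
default_env_window <- function(tissue) {
  tissue <- match.arg(tissue, tissue_levels())
  if (tissue == "red_blood_cell") c(8L, 9L) else c(2L, 3L)
}

## fit one model definition by ML (AIC, loglik) and REML (R2s)
fit_comparison_row <- function(data, response, label, fixed,
                               random_intercepts = c("individual_id",
                                                     "year")) {
  out <- tibble::tibble(
    model = label, akaike_ic = NA_real_, delta_aic = NA_real_,
    r2_marginal = NA_real_, r2_conditional = NA_real_,
    loglik_ml = NA_real_, converged = FALSE, error = NA_character_
  )
  fits <- tryCatch({
    ml <- fit_lmm(data, lmm_spec(response, fixed, random_intercepts,
                                 method = "ML"))
    reml <- fit_lmm(data, lmm_spec(response, fixed, random_intercepts,
                                   method = "REML"))
    r2 <- r2_nakagawa(reml)
    out$akaike_ic <- akaike_ic(ml)
    out$r2_marginal <- r2[["r2_marginal"]]
    out$r2_conditional <- r2[["r2_conditional"]]
    out$loglik_ml <- ml$loglik
    out$converged <- ml$converged && reml$converged
    list(ml = ml, reml = reml)
  }, error = function(e) {
    out$error <<- conditionMessage(e)
    NULL
  })
  list(row = out, fits = fits)
}

finish_comparison <- function(rows, fits, meta) {
  tab <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$akaike_ic)
  tab$delta_aic <- tab$akaike_ic - min(tab$akaike_ic, na.rm = TRUE)
  for (nm in names(meta)) tab[[nm]] <- meta[[nm]]
  tab <- dplyr::relocate(tab, dplyr::all_of(names(meta)))
  attr(tab, "fits") <- fits
  class(tab) <- c("iso_model_comparison", class(tab))
  tab
}

#' Prepare the model frame for the environment-isotope models
#'
#' One row per isotope sample of the tissue, with the window mean of each
#' environmental index in the sampling year joined on, split into
#' within-individual and among-individual parts, plus their squares. The
#' environmental value is shared by all individuals sampled in a year;
#' the among-individual part still varies because individuals are
#' observed in different year subsets.
#'
#' @param ds an [iso_dataset] with an env table.
#' @param tissue,isotope which response series.
#' @param env_names environmental indices to include.
#' @param months window months (default per tissue, see
#'   [default_env_window()]).
#' @return a tibble with `individual_id`, `year`, the response column, and
#'   for each index `E`: `E_within`, `E_between`, `E_within2`,
#'   `E_between2`.
#' @export
prepare_env_model_frame <- function(ds, tissue, isotope,
                                    env_names = NULL, months = NULL) {
  stopifnot(inherits(ds, "iso_dataset"))
  months <- months %||% default_env_window(tissue)
  env_names <- env_names %||% sort(unique(ds$env$index_name))
  frame <- tissue_samples(ds, tissue, isotope)
  names(frame)[names(frame) == "value"] <- isotope
  yrs <- sort(unique(frame$year))
  for (e in env_names) {
    win <- tibble::tibble(
      year = yrs,
      val = env_window_mean(ds$env, e, yrs, months)
    )
    frame <- frame |>
      dplyr::left_join(win, by = "year") |>
      dplyr::rename("{e}" := "val") |>
      center_within_individual(e) |>
      dplyr::mutate(
        "{e}_within2" := .data[[paste0(e, "_within")]]^2,
        "{e}_between2" := .data[[paste0(e, "_between")]]^2
      )
  }
  frame
}

#' Build the environmental model-comparison table for one isotope series
#'
#' Fits, for one tissue x isotope response: a null model (intercept only)
#' and, per environmental index, a linear model (within + between parts)
#' and optionally a quadratic model (adding the squared within and
#' between parts). Every model carries bird identity and year as crossed
#' random intercepts. Each index enters its own model — candidate
#' environmental variables are collinear across the few study years, so
#' joint models are not fitted (see [env_window_correlations()]). AIC is
#' computed from ML fits (REML AICs are not comparable across fixed
#' structures); R-squared values from REML fits.
#'
#' @inheritParams prepare_env_model_frame
#' @param quadratic also fit the quadratic models? (default `TRUE`).
#' @return an `iso_model_comparison` tibble sorted by AIC with columns
#'   `tissue`, `isotope`, `model`, `akaike_ic`, `delta_aic`,
#'   `r2_marginal`, `r2_conditional`, `loglik_ml`, `converged`, `error`.
#'   The fitted models are attached as the `"fits"` attribute, keyed by
#'   model label. Rows whose fit failed carry the message in `error`.
#' @export
build_environment_model_set <- function(ds, tissue, isotope,
                                        env_names = NULL, months = NULL,
                                        quadratic = TRUE) {
  env_names <- env_names %||% sort(unique(ds$env$index_name))
  frame <- prepare_env_model_frame(ds, tissue, isotope, env_names, months)
  defs <- list(list(label = "Null", fixed = character()))
  for (e in env_names) {
    w <- paste0(e, "_within")
    b <- paste0(e, "_between")
    defs <- c(defs, list(list(
      label = sprintf("%s within + between", e), fixed = c(w, b)
    )))
    if (quadratic) {
      defs <- c(defs, list(list(
        label = sprintf("%s within + between + within^2 + between^2", e),
        fixed = c(w, b, paste0(w, "2"), paste0(b, "2"))
      )))
    }
  }
  rows <- list()
  fits <- list()
  for (d in defs) {
    res <- fit_comparison_row(frame, isotope, d$label, d$fixed)
    rows[[d$label]] <- res$row
    fits[[d$label]] <- res$fits
  }
  finish_comparison(rows, fits, list(tissue = tissue, isotope = isotope))
}

#' Test the within-individual effect, then gate the random-slope stage
#'
#' Two-step validation of a fitted within/between model, following the
#' within-subject-centering workflow: first a likelihood-ratio test (ML)
#' of the within-individual fixed effect; only if that effect is
#' significant at `alpha` is the individual random-slope model (slope on
#' the within covariate, independent of the intercepts) fitted and its
#' support reported via a boundary-corrected LRT and the AIC difference.
#' When the within effect is not significant the slope stage is skipped
#' and marked not evaluated — among-individual differences in plasticity
#' are only interpretable once plasticity itself is supported.
#'
#' @param data the prepared model frame (e.g. from
#'   [prepare_env_model_frame()]).
#' @param response response column name.
#' @param within,between the centered covariate column names.
#' @param extra_fixed additional fixed terms kept in both models (e.g.
#'   squared terms).
#' @param alpha significance gate for the within effect (default 0.05).
#' @param random_intercepts crossed random intercept factors.
#' @return a one-row tibble: `p_within`, `within_significant`,
#'   `slope_evaluated`, `slope_variance`, `p_slope`, `slope_delta_aic`,
#'   `slope_supported`.
#' @export
test_within_effect_then_slopes <- function(data, response, within,
                                           between,
                                           extra_fixed = character(),
                                           alpha = 0.05,
                                           random_intercepts =
                                             c("individual_id", "year")) {
  full <- fit_lmm(data, lmm_spec(response,
                                 c(within, between, extra_fixed),
                                 random_intercepts, method = "ML"))
  reduced <- fit_lmm(data, lmm_spec(response, c(between, extra_fixed),
                                    random_intercepts, method = "ML"))
  p_within <- lrt_pvalue(full$loglik, reduced$loglik, df_diff = 1)
  out <- tibble::tibble(
    p_within = p_within,
    within_significant = p_within < alpha,
    slope_evaluated = FALSE,
    slope_variance = NA_real_, p_slope = NA_real_,
    slope_delta_aic = NA_real_, slope_supported = NA
  )
  if (!out$within_significant) return(out)

  slope <- list(group = random_intercepts[1], covariate = within)
  full_slope <- fit_lmm(data, lmm_spec(response,
                                       c(within, between, extra_fixed),
                                       random_intercepts,
                                       random_slope = slope,
                                       method = "ML"))
  p_slope <- lrt_pvalue(full_slope$loglik, full$loglik, df_diff = 1,
                        boundary = TRUE)
  out$slope_evaluated <- TRUE
  out$slope_variance <- full_slope$varcomp[[
    paste0(slope$group, ".slope.", within)]]
  out$p_slope <- p_slope
  out$slope_delta_aic <- akaike_ic(full_slope) - akaike_ic(full)
  out$slope_supported <- p_slope < alpha
  out
}

#' Prepare the model frame linking blood isotopes to breeding traits
#'
#' Joins red-blood-cell isotope values to the breeding-trait table on
#' (individual, year), z-standardizes the trait and the isotope within
#' each year (isotopes, traits and environmental conditions all differ
#' among years), and centers the standardized isotope within individual.
#' Join losses are reported.
#'
#' @param ds an [iso_dataset] with traits.
#' @param trait one of `"body_mass"`, `"clutch_initiation_date"`,
#'   `"total_clutch_mass"`.
#' @param isotope covariate isotope (`"d15N"` or `"d13C"`).
#' @return tibble with `individual_id`, `year`, the standardized trait,
#'   and `<isotope>_within` / `<isotope>_between` columns.
#' @export
prepare_trait_model_frame <- function(ds, trait, isotope) {
  stopifnot(inherits(ds, "iso_dataset"))
  trait <- match.arg(trait, c("body_mass", "clutch_initiation_date",
                              "total_clutch_mass"))
  isotope <- match.arg(isotope, isotope_levels())
  blood <- tissue_samples(ds, "red_blood_cell", isotope)
  names(blood)[names(blood) == "value"] <- isotope
  joined <- dplyr::inner_join(
    blood,
    dplyr::select(ds$traits, dplyr::all_of(c("individual_id", "year",
                                             trait))),
    by = c("individual_id", "year")
  ) |>
    dplyr::filter(!is.na(.data[[trait]]))
  lost <- nrow(blood) - nrow(joined)
  if (lost > 0) {
    inform(sprintf(
      "%d blood record(s) without a matching %s value dropped in join",
      lost, trait
    ))
  }
  joined |>
    standardize_within_year(c(trait, isotope)) |>
    center_within_individual(isotope)
}

#' Build the isotope-to-breeding-trait model-comparison table
#'
#' For one breeding trait: a null model plus one model per isotope
#' covariate, each with the within-individual and among-individual parts
#' of the year-standardized red-blood-cell isotope as fixed effects and
#' bird identity and year as crossed random intercepts. Separate models
#' per isotope are used because blood d15N and d13C are correlated.
#' Likelihood-ratio tests of the within and between effects are attached
#' per model.
#'
#' @inheritParams prepare_trait_model_frame
#' @param isotopes isotope covariates to model (default both).
#' @param alpha gate for the random-slope stage (default 0.05).
#' @return an `iso_model_comparison` tibble (columns as in
#'   [build_environment_model_set()], with `trait` instead of
#'   `tissue`/`isotope`, plus `p_within` and `p_between` per model row).
#'   Effect-test details, including the random-slope gate, are in the
#'   `"effect_tests"` attribute.
#' @export
build_trait_model_set <- function(ds, trait, isotopes = isotope_levels(),
                                  alpha = 0.05) {
  rows <- list()
  fits <- list()
  tests <- list()
  ## the null model frame needs only one isotope's join
  frame0 <- prepare_trait_model_frame(ds, trait, isotopes[1])
  res <- fit_comparison_row(frame0, trait, "Null", character())
  rows[["Null"]] <- res$row
  fits[["Null"]] <- res$fits
  for (iso in isotopes) {
    frame <- prepare_trait_model_frame(ds, trait, iso)
    w <- paste0(iso, "_within")
    b <- paste0(iso, "_between")
    label <- sprintf("%s within + between", iso)
    res <- fit_comparison_row(frame, trait, label, c(w, b))
    rows[[label]] <- res$row
    fits[[label]] <- res$fits
    if (is.null(res$fits)) {
      rows[[label]]$p_within <- NA_real_
      rows[[label]]$p_between <- NA_real_
      next
    }
    gate <- test_within_effect_then_slopes(frame, trait, w, b,
                                           alpha = alpha)
    full_ml <- res$fits$ml
    no_between <- fit_lmm(frame, lmm_spec(trait, w, method = "ML"))
    gate$p_between <- lrt_pvalue(full_ml$loglik, no_between$loglik, 1)
    gate$covariate <- iso
    tests[[label]] <- gate
    rows[[label]]$p_within <- gate$p_within
    rows[[label]]$p_between <- gate$p_between
  }
  tab <- finish_comparison(rows, fits, list(trait = trait))
  attr(tab, "effect_tests") <- dplyr::bind_rows(tests)
  tab
}

#' Plot a model-comparison table
#'
#' Dot plot of delta-AIC per model, annotated with the marginal
#' R-squared.
#'
#' @param object an `iso_model_comparison` tibble.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.iso_model_comparison <- function(object, ...) {
  df <- dplyr::mutate(object,
                      model = factor(.data$model,
                                     levels = rev(.data$model)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_aic, y = .data$model)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("Rm2 = %.3f", .data$r2_marginal)),
      hjust = -0.15, size = 3, na.rm = TRUE
    ) +
    ggplot2::geom_vline(xintercept = 2, linetype = "dashed") +
    ggplot2::labs(x = "delta AIC (ML)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write a model-comparison table as TSV
#'
#' @param tab an `iso_model_comparison` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(tab, path) {
  out <- dplyr::select(
    tibble::as_tibble(tab),
    -dplyr::any_of(c("loglik_ml", "error"))
  )
  readr::write_tsv(out, path)
  invisible(path)
}
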