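#' Within-individual component of the trophic niche (WIC)
#'
#' The unweighted mean, over individuals, of the variance of each
#' individual's repeated isotope measurements for one tissue. Individuals
#' with fewer than `min_samples` measurements of that tissue are excluded
#' (with a warning, or an error if `on_few = "error"`).
#'
#' @param ds an [iso_dataset] or a samples data frame.
#' @param tissue `"red_blood_cell"` or `"feather"`.
#' @param isotope `"d15N"` or `"d13C"`.
#' @param convention `"population"` (n denominator; default — makes
#'   WIC + AIC equal the pooled variance on balanced designs) or
#'   `"sample"` (n - 1).
#' @param min_samples minimum repeated measurements per individual
#'   (default 2).
#' @param on_few `"warn"` (drop the individual) or `"error"`.
#' @param weighted if `TRUE`, weight each individual's variance by its
#'   sample size instead of averaging individuals equally.
#' @return the WIC in per-mil squared.
#' @export
within_individual_component <- function(ds, tissue, isotope,
                                        convention = "population",
                                        min_samples = 2,
                                        on_few = c("warn", "error"),
                                        weighted = FALSE) {
  convention <- check_convention(convention)
  on_few <- match.arg(on_few)
  x <- tissue_samples(ds, tissue, isotope)
  counts <- dplyr::count(x, .data$individual_id)
  few <- counts$individual_id[counts$n < min_samples]
  if (length(few) > 0) {
    msg <- sprintf(
      "%d individual(s) with < %d %s samples excluded from WIC: %s",
      length(few), min_samples, tissue, paste(few, collapse = ", ")
    )
    if (on_few == "error") abort(msg, class = "iso_few_samples_error")
    warn(msg, class = "iso_few_samples_warning")
    x <- dplyr::filter(x, !.data$individual_id %in% few)
  }
  if (nrow(x) == 0) abort("no individuals left for WIC")
  per_ind <- x |>
    dplyr::summarise(
      v = variance_by(.data$value, convention),
      n = dplyr::n(),
      .by = "individual_id"
    )
  if (weighted) {
    sum(per_ind$v * per_ind$n) / sum(per_ind$n)
  } else {
    mean(per_ind$v)
  }
}

#' Among-individual component of the trophic niche (AIC)
#'
#' The variance of the per-individual mean isotope values — how far apart
#' the individuals' average positions sit in isotopic space. Named
#' `aic_niche` in result tables to avoid the collision with the Akaike
#' information criterion.
#'
#' @inheritParams within_individual_component
#' @return the among-individual component in per-mil squared.
#' @export
among_individual_component <- function(ds, tissue, isotope,
                                       convention = "population") {
  convention <- check_convention(convention)
  x <- tissue_samples(ds, tissue, isotope)
  means <- x |>
    dplyr::summarise(m = mean(.data$value), .by = "individual_id")
  if (nrow(means) < 2) {
    abort("among-individual component needs >= 2 individuals",
          class = "iso_too_few_individuals")
  }
  variance_by(means$m, convention)
}

#' Total niche width
#'
#' TNW = WIC + AIC: the population's total isotopic variance decomposes
#' into the within- and among-individual components.
#'
#' @param wic within-individual component (per-mil squared), `>= 0`.
#' @param aic_niche among-individual component (per-mil squared), `>= 0`.
#' @return their sum.
#' @export
total_niche_width <- function(wic, aic_niche) {
  if (any(wic < 0) || any(aic_niche < 0)) {
    abort("niche components must be non-negative")
  }
  wic + aic_niche
}

#' Individual specialization ratio WIC/TNW
#'
#' Ranges over (0, 1]; 1 is a true generalist population (individual
#' niches as broad as the population's), values toward 0 indicate
#' increasing individual specialization.
#'
#' @param wic within-individual component.
#' @param tnw total niche width, `> 0`.
#' @return WIC/TNW, dimensionless.
#' @export
specialization_ratio <- function(wic, tnw) {
  if (any(tnw <= 0)) {
    abort("specialization ratio undefined for TNW <= 0")
  }
  wic / tnw
}

tissue_samples <- function(ds, tissue, isotope) {
  samples <- if (inherits(ds, "iso_dataset")) ds$samples else
    tibble::as_tibble(ds)
  tissue <- match.arg(tissue, tissue_levels())
  isotope <- match.arg(isotope, isotope_levels())
  samples |>
    dplyr::filter(.data$tissue == !!tissue) |>
    dplyr::transmute(
      individual_id = .data$individual_id,
      year = .data$year,
      value = .data[[isotope]]
    )
}

#' Niche-width decomposition for every tissue x isotope combination
#'
#' Computes TNW, WIC, AIC and the WIC/TNW specialization ratio for each
#' tissue and isotope present in the dataset, in one tidy table.
#'
#' @inheritParams within_individual_component
#' @param tissues,isotopes which combinations to decompose (defaults: all).
#' @return a tibble of class `niche_decomposition` with one row per
#'   tissue x isotope: `tissue`, `isotope`, `tnw`, `wic`, `aic_niche`,
#'   `ratio`, `n_individuals`, `n_samples`, `variance_convention`.
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' ds <- generate_dataset(cfg)$dataset
#' niche_decomposition(ds)
#' @export
niche_decomposition <- function(ds, tissues = tissue_levels(),
                                isotopes = isotope_levels(),
                                convention = "population",
                                min_samples = 2, weighted = FALSE) {
  convention <- check_convention(convention)
  grid <- tidyr::expand_grid(tissue = tissues, isotope = isotopes)
  res <- purrr::pmap(grid, function(tissue, isotope) {
    x <- tissue_samples(ds, tissue, isotope)
    wic <- within_individual_component(
      ds, tissue, isotope, convention,
      min_samples = min_samples, weighted = weighted
    )
    aic <- among_individual_component(ds, tissue, isotope, convention)
    tnw <- total_niche_width(wic, aic)
    tibble::tibble(
      tissue = tissue, isotope = isotope,
      tnw = tnw, wic = wic, aic_niche = aic,
      ratio = specialization_ratio(wic, tnw),
      n_individuals = dplyr::n_distinct(x$individual_id),
      n_samples = nrow(x),
      variance_convention = convention
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("niche_decomposition", class(out))
  out
}

#' Write a niche-decomposition table as TSV
#'
#' Emits the conventional presentation: rows TNW, WIC, AIC, WIC/TNW;
#' columns tissue x isotope; values rounded half-up to 2 decimals; a footer
#' with the number of individuals and samples per column.
#'
#' @param nd a [niche_decomposition] tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_niche_table <- function(nd, path) {
  cols <- sprintf("%s %s", nd$tissue, nd$isotope)
  fmt <- function(v) sprintf("%.2f", round_half_up(v, 2))
  body <- rbind(
    c("TNW (permil)", fmt(nd$tnw)),
    c("WIC (permil)", fmt(nd$wic)),
    c("AIC (permil)", fmt(nd$aic_niche)),
    c("WIC/TNW", fmt(nd$ratio)),
    c("n_individuals", as.character(nd$n_individuals)),
    c("n_samples", as.character(nd$n_samples))
  )
  lines <- c(
    paste(c("quantity", cols), collapse = "\t"),
    apply(body, 1, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Plot a niche decomposition
#'
#' Stacked within/among-individual variance components per tissue x
#' isotope, with the WIC/TNW ratio printed above each bar.
#'
#' @param object a [niche_decomposition] tibble.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.niche_decomposition <- function(object, ...) {
  long <- object |>
    dplyr::mutate(series = paste(.data$tissue, .data$isotope)) |>
    tidyr::pivot_longer(c("wic", "aic_niche"),
                        names_to = "component", values_to = "variance") |>
    dplyr::mutate(component = dplyr::recode(
      .data$component,
      wic = "within-individual (WIC)",
      aic_niche = "among-individual (AIC)"
    ))
  labels <- object |>
    dplyr::mutate(series = paste(.data$tissue, .data$isotope))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$series, y = .data$variance,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(
      data = labels,
      ggplot2::aes(x = .data$series, y = .data$tnw,
                   label = sprintf("WIC/TNW = %.2f", .data$ratio)),
      inherit.aes = FALSE, vjust = -0.4, size = 3
    ) +
    ggplot2::labs(x = NULL, y = "isotopic variance (permil squared)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
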