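#' Likelihood-ratio test p-value
#'
#' Compares nested models fit by maximum likelihood. For a test of a
#' single variance component, the null value lies on the boundary of the
#' parameter space and the naive chi-squared reference is conservative;
#' with `boundary = TRUE` the p-value is taken from the
#' 0.5 chi-squared(0) + 0.5 chi-squared(1) mixture instead.
#'
#' @param loglik_full,loglik_reduced ML log-likelihoods of the nested fits.
#' @param df_diff difference in parameter count (must be 1 when
#'   `boundary = TRUE`).
#' @param boundary test of one variance component at its boundary?
#' @return the p-value.
#' @examples
#' lrt_pvalue(-98.0795, -100, 1)            # LR = 3.841 -> 0.05
#' lrt_pvalue(-98.647, -100, 1, boundary = TRUE)
#' @export
lrt_pvalue <- function(loglik_full, loglik_reduced, df_diff = 1,
                       boundary = FALSE) {
  if (boundary && df_diff != 1) {
    abort("boundary correction applies to a single variance component")
  }
  if (df_diff < 1) abort("df_diff must be >= 1")
  lr <- 2 * (loglik_full - loglik_reduced)
  if (lr < -1e-6) {
    abort(sprintf(
      "negative likelihood ratio (%.6g): the full model fit failed", lr
    ), class = "iso_lrt_error")
  }
  lr <- max(lr, 0)
  if (boundary) {
    # the mixture's survival function jumps from 1 to 1/2 at zero; a
    # numerically-zero LR (boundary estimate) belongs to the atom at 0
    if (lr <= 1e-8) 1
    else 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  } else {
    stats::pchisq(lr, df = df_diff, lower.tail = FALSE)
  }
}

#' Akaike information criterion of a mixed-model fit
#'
#' `-2 logLik + 2 k` with `k` = number of fixed-effect coefficients plus
#' number of variance components (including the residual). Comparisons of
#' fixed-effect structures should use ML fits: REML likelihoods of models
#' with different fixed effects are not comparable.
#'
#' @param fit an `iso_lmm`.
#' @return the AIC.
#' @export
akaike_ic <- function(fit) {
  stopifnot(inherits(fit, "iso_lmm"))
  if (!fit$converged) {
    abort("AIC requested for a non-converged fit", class = "iso_fit_error")
  }
  k <- fit$n_fixed + length(fit$varcomp)
  -2 * fit$loglik + 2 * k
}

#' Marginal and conditional R-squared for a mixed model
#'
#' Variance-explained summaries on the total-variance denominator:
#' the marginal R-squared is the share explained by fixed effects alone,
#' the conditional R-squared the share explained by fixed plus random
#' effects. The fixed-effect variance is the variance of the fixed linear
#' predictor over the observations; a random slope contributes its
#' variance times the mean squared covariate.
#'
#' @param fit a converged `iso_lmm` containing an intercept.
#' @return named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "iso_lmm"))
  sigma_f <- stats::var(fit$fitted_fixed)
  k <- names(fit$varcomp)
  rand <- k[k != "residual"]
  sigma_rand <- sum(fit$varcomp[rand] * fit$mean_sq[rand])
  denom <- sigma_f + sigma_rand + fit$varcomp[["residual"]]
  if (denom <= 0) abort("zero total variance: R-squared undefined")
  c(r2_marginal = sigma_f / denom,
    r2_conditional = (sigma_f + sigma_rand) / denom)
}

#' Among-group repeatability (intraclass correlation)
#'
#' Agreement repeatability R = sigma2_group / (sigma2_group + sigma2_res)
#' from an intercept-only REML fit with a single random grouping factor —
#' here, the among-year consistency of an individual's isotope values. The
#' standard error comes from a parametric bootstrap (simulate from the
#' fitted model on the observed design, refit, take the SD of the
#' bootstrap R values); the p-value from a boundary-corrected
#' likelihood-ratio test of the group variance (ML fits).
#'
#' @param data data frame with the response and grouping columns.
#' @param response name of the response column.
#' @param grouping name of the grouping-factor column (e.g.
#'   `individual_id`).
#' @param n_boot parametric-bootstrap replicates for the SE (default 1000;
#'   0 skips the bootstrap and returns `NA` SE).
#' @param seed integer seed for the bootstrap (RNG state is restored).
#' @param adjusted_for optional fixed covariates (e.g. `"year_factor"`)
#'   for an adjusted repeatability; default none (agreement
#'   repeatability).
#' @return a one-row tibble of class `iso_repeatability`: `r`, `se`,
#'   `p_value`, `sigma2_group`, `sigma2_residual`, `n_obs`, `n_groups`,
#'   `n_boot`, `seed`.
#' @export
repeatability <- function(data, response, grouping = "individual_id",
                          n_boot = 1000, seed = 1L,
                          adjusted_for = character()) {
  data <- as.data.frame(data)
  y <- data[[response]]
  f <- factor(data[[grouping]])
  keep <- !is.na(y)
  y <- y[keep]
  data <- data[keep, , drop = FALSE]
  f <- droplevels(f[keep])
  if (nlevels(f) < 2 || length(y) < 4) {
    abort("repeatability needs >= 2 groups and >= 4 observations")
  }
  if (stats::var(y) < 1e-14) {
    abort("response has zero variance: repeatability undefined",
          class = "iso_degenerate_data")
  }
  spec_reml <- lmm_spec(response, fixed = adjusted_for,
                        random_intercepts = grouping, method = "REML")
  fit <- fit_lmm(data, spec_reml)
  s2g <- fit$varcomp[[grouping]]
  s2e <- fit$varcomp[["residual"]]
  r <- s2g / (s2g + s2e)

  ## boundary LRT, ML fits
  full_ml <- fit_lmm(data, lmm_spec(response, fixed = adjusted_for,
                                    random_intercepts = grouping,
                                    method = "ML"))
  reduced_ll <- ols_loglik(data, response, adjusted_for)
  p <- lrt_pvalue(full_ml$loglik, reduced_ll, df_diff = 1, boundary = TRUE)

  se <- NA_real_
  if (n_boot > 0) {
    mu_hat <- fit$fitted_fixed
    se <- with_preserved_seed(seed, {
      rs <- vapply(seq_len(n_boot), function(b) {
        bsim <- data
        bsim[[response]] <- mu_hat +
          rnorm(nlevels(f), 0, sqrt(s2g))[as.integer(f)] +
          rnorm(length(y), 0, sqrt(s2e))
        bfit <- fit_lmm(bsim, spec_reml)
        v <- bfit$varcomp
        v[[grouping]] / (v[[grouping]] + v[["residual"]])
      }, numeric(1))
      stats::sd(rs)
    })
  }
  out <- tibble::tibble(
    r = r, se = se, p_value = p,
    sigma2_group = s2g, sigma2_residual = s2e,
    n_obs = length(y), n_groups = nlevels(f),
    n_boot = n_boot, seed = as.integer(seed)
  )
  class(out) <- c("iso_repeatability", class(out))
  out
}

## exact Gaussian OLS log-likelihood (the no-random-effect reduced model)
ols_loglik <- function(data, response, fixed = character()) {
  y <- data[[response]]
  X <- if (length(fixed) == 0) {
    matrix(1, length(y), 1)
  } else {
    stats::model.matrix(stats::reformulate(fixed, intercept = TRUE),
                        data = data)
  }
  e <- stats::lm.fit(X, y)$residuals
  n <- length(y)
  s2 <- sum(e^2) / n
  -n / 2 * (log(2 * pi * s2) + 1)
}

## run code under a given seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Approximate Wald F statistic for a set of fixed-effect columns
#'
#' A convenience summary using the residual-containment denominator
#' degrees of freedom (n_obs - fixed-effect columns - number of random
#' terms). It is approximate; likelihood-ratio tests are the primary
#' inference path.
#'
#' @param fit an `iso_lmm`.
#' @param terms names of coefficient columns to test jointly (as they
#'   appear in `names(fit$beta)`).
#' @return a one-row tibble: `statistic`, `df1`, `df2`, `p_value`,
#'   `approximate = TRUE`.
#' @export
wald_f <- function(fit, terms) {
  stopifnot(inherits(fit, "iso_lmm"))
  idx <- match(terms, names(fit$beta))
  if (anyNA(idx)) abort("unknown coefficient name(s)")
  b <- fit$beta[idx]
  V <- fit$vcov_beta[idx, idx, drop = FALSE]
  stat <- drop(crossprod(b, solve(V, b))) / length(idx)
  df2 <- fit$n_obs - fit$n_fixed - (length(fit$varcomp) - 1)
  tibble::tibble(
    statistic = stat, df1 = length(idx), df2 = df2,
    p_value = stats::pf(stat, length(idx), df2, lower.tail = FALSE),
    approximate = TRUE
  )
}
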