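#' Specify a Gaussian linear mixed model
#'
#' Describes a model for [fit_lmm()]: a numeric response, fixed-effect
#' terms (columns of the data, possibly factors or precomputed squared
#' terms), crossed random intercepts, and at most one independent random
#' slope. The typical model here is an isotope or breeding trait with
#' `individual_id` and `year` as crossed random intercepts.
#'
#' @param response name of the response column.
#' @param fixed character vector of fixed-effect term names (an intercept
#'   is always included; `character()` gives the null model).
#' @param random_intercepts character vector of grouping-factor columns,
#'   each contributing an independent random intercept.
#' @param random_slope optional `list(group =, covariate =)`: an
#'   individual-level random slope on `covariate`, independent of the
#'   intercepts.
#' @param method `"REML"` (variance components corrected for fixed-effect
#'   estimation; the default for reporting) or `"ML"` (required for
#'   likelihood-ratio tests and AIC comparison of fixed structures).
#' @return an object of class `lmm_spec`.
#' @export
lmm_spec <- function(response, fixed = character(),
                     random_intercepts = c("individual_id", "year"),
                     random_slope = NULL,
                     method = c("REML", "ML")) {
  method <- match.arg(method)
  if (anyDuplicated(fixed)) abort("duplicated fixed-effect terms")
  if (anyDuplicated(random_intercepts)) abort("duplicated random terms")
  if (!is.null(random_slope) &&
      !all(c("group", "covariate") %in% names(random_slope))) {
    abort("random_slope must be list(group =, covariate =)")
  }
  structure(
    list(response = response, fixed = fixed,
         random_intercepts = random_intercepts,
         random_slope = random_slope, method = method),
    class = "lmm_spec"
  )
}

## random-effect design matrices + labels for a spec on given data
build_random_designs <- function(data, spec) {
  Z <- list()
  for (g in spec$random_intercepts) {
    f <- factor(data[[g]])
    if (nlevels(f) < 2) {
      abort(sprintf("grouping factor '%s' has < 2 levels", g))
    }
    Zg <- stats::model.matrix(~ 0 + f)
    colnames(Zg) <- levels(f)
    Z[[g]] <- Zg
  }
  if (!is.null(spec$random_slope)) {
    g <- spec$random_slope$group
    w <- data[[spec$random_slope$covariate]]
    f <- factor(data[[g]])
    Zs <- stats::model.matrix(~ 0 + f) * w
    Z[[paste0(g, ".slope.", spec$random_slope$covariate)]] <- Zs
  }
  Z
}

## negative profiled log-likelihood on the dense path.
## th: sd ratios (sigma_k / sigma_eps), A: list of Z_k Z_k'
neg_profile_ll <- function(th, A, X, y, method) {
  n <- length(y)
  p <- ncol(X)
  V0 <- diag(n)
  for (k in seq_along(A)) V0 <- V0 + th[k]^2 * A[[k]]
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  ldet <- 2 * sum(log(diag(R)))
  Xt <- backsolve(R, X, transpose = TRUE)
  yt <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Xt)
  cXtX <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(cXtX)) return(1e10)
  beta <- backsolve(cXtX, backsolve(cXtX, crossprod(Xt, yt),
                                    transpose = TRUE))
  e <- yt - Xt %*% beta
  q <- sum(e^2)
  if (q <= 0) q <- .Machine$double.eps
  if (method == "ML") {
    s2 <- q / n
    0.5 * (n * log(2 * pi) + ldet + n * log(s2) + n)
  } else {
    s2 <- q / (n - p)
    ldet_XtX <- 2 * sum(log(diag(cXtX)))
    0.5 * ((n - p) * log(2 * pi) + ldet + ldet_XtX +
             (n - p) * log(s2) + (n - p))
  }
}

## GLS quantities at a given th (dense path)
gls_at <- function(th, A, X, y, method) {
  n <- length(y)
  p <- ncol(X)
  V0 <- diag(n)
  for (k in seq_along(A)) V0 <- V0 + th[k]^2 * A[[k]]
  R <- chol(V0)
  Xt <- backsolve(R, X, transpose = TRUE)
  yt <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Xt)
  beta <- drop(solve(XtX, crossprod(Xt, yt)))
  q <- sum((yt - Xt %*% beta)^2)
  s2 <- if (method == "ML") q / n else q / (n - p)
  list(beta = beta, sigma2 = s2, vcov_beta = solve(XtX) * s2)
}

#' Fit a Gaussian linear mixed model by REML or ML
#'
#' Maximizes the (restricted) Gaussian log-likelihood over non-negative
#' variance components for a model with crossed random intercepts and an
#' optional independent random slope. Fixed effects and the residual
#' variance are profiled out analytically; the remaining variance ratios
#' are optimized on the standard-deviation-ratio scale with a lower bound
#' of zero, from two starting points to reduce local-optimum risk. Designs
#' with a single random intercept use an exact closed-form profile (the
#' marginal covariance is block diagonal), which makes repeatability
#' bootstraps cheap; general crossed designs use a dense marginal
#' covariance, suitable for up to a few thousand observations.
#'
#' Boundary (zero) variance estimates are legitimate outcomes and are
#' flagged via `singular` rather than treated as failures.
#'
#' @param data a data frame containing the response, fixed-effect and
#'   grouping columns.
#' @param spec an [lmm_spec], or arguments to construct one via `...`.
#' @param ... passed to [lmm_spec()] when `spec` is missing.
#' @return an object of class `iso_lmm`: coefficient estimates with
#'   standard errors, variance components (one per random term plus
#'   `residual`), the maximized log-likelihood, convergence flags, and the
#'   ingredients for [r2_nakagawa()].
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' ds <- generate_dataset(cfg)$dataset
#' blood <- dplyr::filter(ds$samples, tissue == "red_blood_cell")
#' fit <- fit_lmm(blood, lmm_spec("d15N", method = "REML"))
#' tidy(fit)
#' glance(fit)
#' @export
fit_lmm <- function(data, spec = NULL, ...) {
  if (is.null(spec)) spec <- lmm_spec(...)
  stopifnot(inherits(spec, "lmm_spec"))
  data <- as.data.frame(data)

  y <- data[[spec$response]]
  if (is.null(y)) abort(sprintf("response '%s' not found", spec$response))
  X <- if (length(spec$fixed) == 0) {
    matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(stats::reformulate(spec$fixed, intercept = TRUE),
                        data = data)
  }
  n <- length(y)
  p <- ncol(X)
  if (n <= p) abort("more fixed-effect columns than observations")

  Z <- build_random_designs(data, spec)
  K <- length(Z)
  term_names <- names(Z)
  ## mean squared row norm of each Z_k: the per-observation variance
  ## multiplier used by the conditional R-squared (1 for intercepts,
  ## mean(w^2) for a slope)
  mean_sq <- vapply(Z, function(z) mean(rowSums(z^2)), numeric(1))

  ## degenerate response: nothing to estimate
  if (stats::var(y) < 1e-14) {
    g <- list(beta = c(`(Intercept)` = mean(y)), sigma2 = 0)
    vc <- setNames(rep(0, K + 1), c(term_names, "residual"))
    return(new_iso_lmm(spec, g$beta,
                       setNames(rep(0, p), colnames(X)), vc,
                       loglik = Inf, n = n, p = p, converged = TRUE,
                       singular = TRUE, X = X, mean_sq = mean_sq,
                       vcov_beta = matrix(0, p, p)))
  }

  single_intercept <- K == 1 && is.null(spec$random_slope)
  if (single_intercept) {
    fit <- fit_one_factor(X, y, factor(data[[spec$random_intercepts]]),
                          spec$method)
    th_hat <- sqrt(fit$gamma)
    opt_val <- fit$nll
    converged <- TRUE
  } else {
    A <- lapply(Z, tcrossprod)
    obj <- function(th) neg_profile_ll(th, A, X, y, spec$method)
    starts <- list(rep(1, K), rep(0.1, K))
    best <- NULL
    for (s in starts) {
      o <- stats::optim(s, obj, method = "L-BFGS-B",
                        lower = rep(0, K), upper = rep(100, K),
                        control = list(factr = 1e4, maxit = 500))
      if (is.null(best) || o$value < best$value) best <- o
    }
    ## polish with a derivative-free pass (folded to keep th >= 0);
    ## L-BFGS-B's numeric gradient is unreliable on the flat boundary
    polish <- stats::optim(best$par, function(p) obj(abs(p)),
                           method = "Nelder-Mead",
                           control = list(maxit = 1000,
                                          reltol = 1e-12))
    th_hat <- abs(polish$par)
    opt_val <- polish$value
    converged <- polish$convergence == 0 ||
      abs(best$value - polish$value) < 1e-6 * (1 + abs(polish$value))
  }

  g <- if (single_intercept) {
    gls_one_factor(X, y, factor(data[[spec$random_intercepts]]),
                   th_hat^2, spec$method)
  } else {
    gls_at(th_hat, lapply(Z, tcrossprod), X, y, spec$method)
  }
  vc <- setNames(c(th_hat^2 * g$sigma2, g$sigma2),
                 c(term_names, "residual"))
  singular <- any(th_hat < 1e-4)
  beta <- setNames(drop(g$beta), colnames(X))
  se <- setNames(sqrt(pmax(diag(g$vcov_beta), 0)), colnames(X))
  new_iso_lmm(spec, beta, se, vc, loglik = -opt_val, n = n, p = p,
              converged = converged, singular = singular, X = X,
              mean_sq = mean_sq, vcov_beta = g$vcov_beta)
}

new_iso_lmm <- function(spec, beta, se, varcomp, loglik, n, p,
                        converged, singular, X, mean_sq, vcov_beta) {
  structure(
    list(spec = spec, beta = beta, se_beta = se, varcomp = varcomp,
         loglik = loglik, n_obs = n, n_fixed = p, converged = converged,
         singular = singular, fitted_fixed = drop(X %*% beta),
         mean_sq = mean_sq, vcov_beta = vcov_beta),
    class = "iso_lmm"
  )
}

## ---- exact profile for a single random intercept ----
## V0 = I + gamma Z Z' is block diagonal by group, so every GLS quantity
## reduces to per-group sums; each likelihood evaluation is O(n p^2).
one_factor_parts <- function(X, y, f) {
  idx <- split(seq_along(y), f)
  G <- length(idx)
  p <- ncol(X)
  S <- matrix(0, G, p)           # per-group column sums of X
  ysum <- numeric(G)
  for (g in seq_len(G)) {
    S[g, ] <- colSums(X[idx[[g]], , drop = FALSE])
    ysum[g] <- sum(y[idx[[g]]])
  }
  list(XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2),
       S = S, ysum = ysum, ng = lengths(idx), n = length(y), p = p)
}

one_factor_nll <- function(gamma, parts, method) {
  cg <- gamma / (1 + gamma * parts$ng)
  XtViX <- parts$XtX - crossprod(parts$S * sqrt(cg))
  XtViy <- drop(parts$Xty) - colSums(parts$S * (cg * parts$ysum))
  ytViy <- parts$yty - sum(cg * parts$ysum^2)
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(1e10)
  beta <- backsolve(cX, backsolve(cX, XtViy, transpose = TRUE))
  q <- ytViy - 2 * sum(beta * XtViy) + drop(crossprod(beta, XtViX %*% beta))
  if (q <= 0) q <- .Machine$double.eps
  ldet <- sum(log1p(gamma * parts$ng))
  n <- parts$n
  p <- parts$p
  if (method == "ML") {
    0.5 * (n * log(2 * pi) + ldet + n * log(q / n) + n)
  } else {
    0.5 * ((n - p) * log(2 * pi) + ldet + 2 * sum(log(diag(cX))) +
             (n - p) * log(q / (n - p)) + (n - p))
  }
}

fit_one_factor <- function(X, y, f, method) {
  parts <- one_factor_parts(X, y, f)
  obj <- function(t) one_factor_nll(exp(t), parts, method)
  o <- stats::optimize(obj, interval = c(-30, 12), tol = 1e-10)
  nll0 <- one_factor_nll(0, parts, method)
  if (nll0 <= o$objective + 1e-8) {
    list(gamma = 0, nll = nll0)
  } else {
    list(gamma = exp(o$minimum), nll = o$objective)
  }
}

gls_one_factor <- function(X, y, f, gamma, method) {
  parts <- one_factor_parts(X, y, f)
  cg <- gamma / (1 + gamma * parts$ng)
  XtViX <- parts$XtX - crossprod(parts$S * sqrt(cg))
  XtViy <- drop(parts$Xty) - colSums(parts$S * (cg * parts$ysum))
  ytViy <- parts$yty - sum(cg * parts$ysum^2)
  beta <- drop(solve(XtViX, XtViy))
  q <- ytViy - 2 * sum(beta * XtViy) + drop(crossprod(beta, XtViX %*% beta))
  s2 <- if (method == "ML") q / parts$n else q / (parts$n - parts$p)
  list(beta = beta, sigma2 = s2, vcov_beta = solve(XtViX) * s2)
}

#' @export
print.iso_lmm <- function(x, ...) {
  cat(sprintf("<iso_lmm> %s ~ %s  (%s, n = %d)\n",
              x$spec$response,
              if (length(x$spec$fixed)) paste(x$spec$fixed, collapse = " + ")
              else "1",
              x$spec$method, x$n_obs))
  cat("random:", paste(names(x$varcomp), collapse = ", "), "\n")
  cat(sprintf("logLik %.3f%s%s\n", x$loglik,
              if (!x$converged) "  [NOT CONVERGED]" else "",
              if (x$singular) "  [singular fit]" else ""))
  print(round(x$beta, 4))
  invisible(x)
}

#' Tidy a fitted mixed model
#'
#' @param x an `iso_lmm` fit.
#' @param effects `"fixed"`, `"ran_pars"`, or both.
#' @param ... ignored.
#' @return a tibble with one row per term: fixed effects carry `estimate`,
#'   `std.error` and `statistic` (Wald z); variance components carry the
#'   estimated variance in `estimate`.
#' @export
tidy.iso_lmm <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects, several.ok = TRUE)
  out <- list()
  if ("fixed" %in% effects) {
    out$fixed <- tibble::tibble(
      effect = "fixed", term = names(x$beta),
      estimate = unname(x$beta), std.error = unname(x$se_beta),
      statistic = unname(x$beta / x$se_beta)
    )
  }
  if ("ran_pars" %in% effects) {
    out$ran <- tibble::tibble(
      effect = "ran_pars",
      term = paste0("var_", names(x$varcomp)),
      estimate = unname(x$varcomp),
      std.error = NA_real_, statistic = NA_real_
    )
  }
  dplyr::bind_rows(out)
}

#' One-row summary of a fitted mixed model
#'
#' @param x an `iso_lmm` fit.
#' @param ... ignored.
#' @return a one-row tibble: `logLik`, `AIC`, `r2_marginal`,
#'   `r2_conditional`, `sigma` (residual SD), `n_obs`, `converged`,
#'   `singular`.
#' @export
glance.iso_lmm <- function(x, ...) {
  r2 <- tryCatch(r2_nakagawa(x), error = function(e) c(NA_real_, NA_real_))
  tibble::tibble(
    logLik = x$loglik,
    AIC = tryCatch(akaike_ic(x), error = function(e) NA_real_),
    r2_marginal = r2[[1]], r2_conditional = r2[[2]],
    sigma = sqrt(x$varcomp[["residual"]]),
    n_obs = x$n_obs, converged = x$converged, singular = x$singular
  )
}
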