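test_that("balanced one-way REML reproduces the ANOVA closed form", {
  set.seed(21)
  for (rep in 1:3) {
    a <- 8
    n <- 5
    df <- make_one_way(a, n, sd_g = 1.5, sd_e = 0.8)
    fit <- fit_lmm(df, lmm_spec("y", random_intercepts = "individual_id",
                                method = "REML"))
    ag <- stats::aov(y ~ individual_id, data = df)
    ms <- summary(ag)[[1]]$`Mean Sq`
    msb <- ms[1]
    msw <- ms[2]
    expect_equal(fit$varcomp[["residual"]], msw, tolerance = 1e-6)
    expect_equal(fit$varcomp[["individual_id"]],
                 max((msb - msw) / n, 0), tolerance = 1e-6)

    # ML shrinks the between component by (a-1)/a
    fml <- fit_lmm(df, lmm_spec("y", random_intercepts = "individual_id",
                                method = "ML"))
    s2a_ml <- max(((a - 1) / a) * msb - msw, 0) / n
    expect_equal(fml$varcomp[["individual_id"]], s2a_ml, tolerance = 1e-5)
  }
})

test_that("with no grouping structure the fit collapses to OLS", {
  set.seed(5)
  df <- tibble::tibble(
    individual_id = rep(sprintf("G%02d", 1:20), each = 3),
    x = rnorm(60),
    y = 1 + 0.5 * rnorm(60)  # y independent of the grouping
  )
  df$y <- 2 + 0.3 * df$x + rnorm(60, 0, 1)
  # scramble groups so they carry no signal
  df$individual_id <- sample(df$individual_id)
  fit <- fit_lmm(df, lmm_spec("y", "x", random_intercepts = "individual_id",
                              method = "ML"))
  ols <- stats::lm(y ~ x, data = df)
  ll_ols <- as.numeric(stats::logLik(ols))
  expect_lte(fit$varcomp[["individual_id"]], 1e-6 * fit$varcomp[["residual"]])
  expect_equal(fit$loglik, ll_ols, tolerance = 1e-6)
  expect_true(fit$singular)
})

test_that("crossed and random-slope fits agree with an independent REML/ML implementation", {
  cfg <- synthetic_config(seed = 11, beta_within = 0.6,
                          beta_between = -0.4, slope_sd = 0.8)
  x <- generate_dataset(cfg)
  fr <- prepare_env_model_frame(x$dataset, "red_blood_cell", "d15N", "SAM")
  for (method in c("REML", "ML")) {
    fit <- fit_lmm(fr, lmm_spec("d15N", c("SAM_within", "SAM_between"),
                                method = method))
    ref <- lme4::lmer(
      d15N ~ SAM_within + SAM_between + (1 | individual_id) + (1 | year),
      data = fr, REML = method == "REML"
    )
    expect_equal(fit$loglik, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(fit$beta), unname(lme4::fixef(ref)),
                 tolerance = 1e-4)
    vc <- as.data.frame(lme4::VarCorr(ref))
    expect_equal(fit$varcomp[["individual_id"]],
                 vc$vcov[vc$grp == "individual_id"], tolerance = 1e-4)
    expect_equal(fit$varcomp[["residual"]],
                 vc$vcov[vc$grp == "Residual"], tolerance = 1e-4)
  }
  # independent random slope on the within covariate
  fs <- fit_lmm(fr, lmm_spec(
    "d15N", c("SAM_within", "SAM_between"),
    random_slope = list(group = "individual_id", covariate = "SAM_within"),
    method = "ML"
  ))
  rs <- lme4::lmer(
    d15N ~ SAM_within + SAM_between + (1 | individual_id) + (1 | year) +
      (0 + SAM_within | individual_id),
    data = fr, REML = FALSE
  )
  expect_equal(fs$loglik, as.numeric(stats::logLik(rs)), tolerance = 1e-5)
})

test_that("a constant response gives a degenerate but flagged fit", {
  df <- tibble::tibble(individual_id = rep(c("a", "b"), each = 3),
                       y = 5)
  fit <- fit_lmm(df, lmm_spec("y", random_intercepts = "individual_id"))
  expect_equal(unname(fit$beta), 5)
  expect_equal(unname(fit$varcomp), c(0, 0))
  expect_true(fit$singular)
})

test_that("ML likelihood never decreases when a fixed effect is added", {
  set.seed(31)
  for (rep in 1:5) {
    cfg <- synthetic_config(seed = 100 + rep)
    x <- generate_dataset(cfg)
    fr <- prepare_env_model_frame(x$dataset, "red_blood_cell", "d13C",
                                  "SOI")
    null <- fit_lmm(fr, lmm_spec("d13C", method = "ML"))
    lin <- fit_lmm(fr, lmm_spec("d13C", c("SOI_within", "SOI_between"),
                                method = "ML"))
    expect_gte(lin$loglik, null$loglik - 1e-8)
  }
})

test_that("likelihood-ratio p-values match chi-squared tail oracles", {
  expect_equal(lrt_pvalue(-100, -100, 1), 1)
  expect_equal(lrt_pvalue(-100 + 3.841 / 2, -100, 1),
               pchisq(3.841, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(lrt_pvalue(-100 + 3.841 / 2, -100, 1), 4), 0.05)
  # boundary mixture: half the chi2_1 tail
  expect_equal(lrt_pvalue(-100 + 2.706 / 2, -100, 1, boundary = TRUE),
               0.5 * pchisq(2.706, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(lrt_pvalue(-100 + 2.706 / 2, -100, 1,
                                boundary = TRUE), 4), 0.05)
  expect_equal(lrt_pvalue(-100, -100, 1, boundary = TRUE), 1)
  expect_error(lrt_pvalue(-101, -100, 1), class = "iso_lrt_error")
  expect_error(lrt_pvalue(-99, -100, 2, boundary = TRUE))
})

test_that("AIC counts fixed effects plus variance components", {
  set.seed(3)
  df <- make_one_way(6, 4)
  fit <- fit_lmm(df, lmm_spec("y", random_intercepts = "individual_id",
                              method = "ML"))
  # k = 1 fixed + 2 variance components
  expect_equal(akaike_ic(fit), -2 * fit$loglik + 2 * 3)
  bad <- fit
  bad$converged <- FALSE
  expect_error(akaike_ic(bad), class = "iso_fit_error")
})

test_that("marginal/conditional R2 follow the variance-share formulas", {
  # constructed fit: var(fixed predictor) = 1, sigma2_ind = 1, sigma2_eps = 2
  fake <- structure(list(
    spec = lmm_spec("y"),
    beta = c(`(Intercept)` = 0),
    varcomp = c(individual_id = 1, residual = 2),
    fitted_fixed = c(-1, 0, 1) * sqrt(1 / 1),
    mean_sq = c(individual_id = 1),
    n_obs = 3, n_fixed = 1, converged = TRUE
  ), class = "iso_lmm")
  r2 <- r2_nakagawa(fake)
  expect_equal(unname(r2), c(0.25, 0.50), tolerance = 1e-12)

  # intercept-only -> Rm2 = 0; no random variance -> Rc2 = Rm2
  set.seed(8)
  df <- make_one_way(8, 4)
  fit0 <- fit_lmm(df, lmm_spec("y", random_intercepts = "individual_id"))
  r20 <- r2_nakagawa(fit0)
  expect_equal(unname(r20[["r2_marginal"]]), 0)
  fake2 <- fake
  fake2$varcomp <- c(individual_id = 0, residual = 2)
  r22 <- r2_nakagawa(fake2)
  expect_equal(r22[["r2_marginal"]], r22[["r2_conditional"]])

  # invariance of Rm2 to affine rescaling of the response
  cfg <- synthetic_config(seed = 4, beta_within = 0.8)
  x <- generate_dataset(cfg)
  fr <- prepare_env_model_frame(x$dataset, "red_blood_cell", "d15N", "SAM")
  f1 <- fit_lmm(fr, lmm_spec("d15N", c("SAM_within", "SAM_between")))
  fr2 <- dplyr::mutate(fr, d15N = 3 * d15N + 100)
  f2 <- fit_lmm(fr2, lmm_spec("d15N", c("SAM_within", "SAM_between")))
  expect_equal(r2_nakagawa(f1)[["r2_marginal"]],
               r2_nakagawa(f2)[["r2_marginal"]], tolerance = 1e-5)
})

test_that("variance components are recovered across seeded simulations", {
  # at the study design scale (30 individuals, 7 crossed years, ~130 obs)
  # the REML estimator is unbiased for every component, and the residual
  # (the only component with many effective degrees of freedom) also has
  # small per-replicate error; the individual and year components carry
  # irreducible sampling spread from their 30 and 7 levels
  reps <- 200
  est <- matrix(NA_real_, reps, 3)
  truth <- c(individual = 0.54, year = 0.30, residual = 0.29)
  for (r in seq_len(reps)) {
    x <- generate_dataset(synthetic_config(seed = 5000 + r))
    blood <- dplyr::filter(x$dataset$samples, tissue == "red_blood_cell")
    fit <- fit_lmm(blood, lmm_spec("d15N", method = "REML"))
    est[r, ] <- fit$varcomp[c("individual_id", "year", "residual")]
  }
  means <- colMeans(est)
  expect_lt(abs(means[1] / truth[1] - 1), 0.10)
  expect_lt(abs(means[2] / truth[2] - 1), 0.15)
  expect_lt(abs(means[3] / truth[3] - 1), 0.05)
  rel_err <- abs(sweep(est, 2, truth, "/") - 1)
  expect_lt(median(rel_err[, 3]), 0.15)
})

test_that("repeatability handles perfect, absent and adjusted cases", {
  # perfectly consistent groups -> r ~ 1
  df <- tibble::tibble(individual_id = rep(c("a", "b", "c"), each = 4),
                       y = rep(c(1, 2, 4), each = 4))
  r1 <- repeatability(df, "y", n_boot = 0)
  expect_gt(r1$r, 0.999)

  # group means exactly equal by construction -> r = 0, boundary p = 1
  df0 <- tibble::tibble(
    individual_id = rep(sprintf("G%02d", 1:20), each = 4),
    y = rep(c(-1.3, -0.2, 0.4, 1.1), times = 20)
  )
  r0 <- repeatability(df0, "y", n_boot = 0)
  expect_lt(r0$r, 1e-6)
  expect_equal(r0$p_value, 1)

  # degenerate data errors
  expect_error(repeatability(dplyr::mutate(df0, y = 1), "y", n_boot = 0),
               class = "iso_degenerate_data")

  # bootstrap SE is reproducible under the same seed and plausible in size
  set.seed(77)
  dfr <- make_one_way(30, 4, sd_g = 1, sd_e = 1)
  ra <- repeatability(dfr, "y", n_boot = 100, seed = 9)
  rb <- repeatability(dfr, "y", n_boot = 100, seed = 9)
  expect_identical(ra$se, rb$se)
  expect_gt(ra$se, 0.01)
  expect_lt(ra$se, 0.3)
})

test_that("approximate Wald F detects a strong year effect", {
  cfg <- synthetic_config(seed = 19)  # sigma2_year > 0 by default
  x <- generate_dataset(cfg)
  blood <- dplyr::filter(x$dataset$samples, tissue == "red_blood_cell") |>
    dplyr::mutate(year_f = factor(year))
  fit <- fit_lmm(blood, lmm_spec("d15N", "year_f",
                                 random_intercepts = "individual_id"))
  terms <- grep("^year_f", names(fit$beta), value = TRUE)
  wf <- wald_f(fit, terms)
  expect_equal(wf$df1, length(unique(blood$year)) - 1)
  expect_true(wf$approximate)
  expect_lt(wf$p_value, 0.05)
})
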