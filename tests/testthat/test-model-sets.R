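test_that("environment model tables have the declared shape", {
  x <- generate_dataset(synthetic_config(seed = 9))
  tab <- build_environment_model_set(x$dataset, "red_blood_cell", "d15N")
  # null + 3 indices x (linear, quadratic)
  expect_equal(nrow(tab), 7)
  expect_true("Null" %in% tab$model)
  expect_equal(tab$delta_aic[1], 0)
  expect_true(all(diff(tab$delta_aic) >= 0))      # sorted ascending
  expect_equal(tab$akaike_ic - min(tab$akaike_ic), tab$delta_aic)
  expect_true(all(tab$r2_marginal >= 0 & tab$r2_marginal <= 1,
                  na.rm = TRUE))
  expect_true(all(tab$r2_conditional >= tab$r2_marginal - 1e-10,
                  na.rm = TRUE))
  # null model explains nothing by fixed effects
  expect_equal(tab$r2_marginal[tab$model == "Null"], 0)

  # single null model requested -> one row with delta 0
  solo <- build_environment_model_set(x$dataset, "red_blood_cell", "d15N",
                                      env_names = character())
  expect_equal(nrow(solo), 1)
  expect_equal(solo$delta_aic, 0)

  # quadratic labels square the centered covariates
  expect_true(any(grepl("within\\^2", tab$model)))
})

test_that("a strong within-individual effect beats the null by AIC", {
  # the environmental effect is the source of among-year variation here
  # (no independent year variance, which would confound a year-level
  # covariate fitted alongside a year random intercept)
  wins <- vapply(1:100, function(seed) {
    cfg <- synthetic_config(seed = 2000 + seed, beta_within = 1,
                            sigma2_year = 0, sigma2_residual = 0.25)
    x <- generate_dataset(cfg)
    fr <- prepare_env_model_frame(x$dataset, "red_blood_cell", "d15N",
                                  "SAM")
    null <- fit_lmm(fr, lmm_spec("d15N", method = "ML"))
    lin <- fit_lmm(fr, lmm_spec("d15N", c("SAM_within", "SAM_between"),
                                method = "ML"))
    akaike_ic(null) - akaike_ic(lin) > 2
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("under a null environment the null model stays competitive", {
  close_to_best <- vapply(1:100, function(seed) {
    cfg <- synthetic_config(seed = 3000 + seed)  # beta = 0 defaults
    x <- generate_dataset(cfg)
    fr <- prepare_env_model_frame(x$dataset, "red_blood_cell", "d13C",
                                  "SAM")
    null <- fit_lmm(fr, lmm_spec("d13C", method = "ML"))
    lin <- fit_lmm(fr, lmm_spec("d13C", c("SAM_within", "SAM_between"),
                                method = "ML"))
    akaike_ic(null) - min(akaike_ic(null), akaike_ic(lin)) <= 2
  }, logical(1))
  expect_gte(mean(close_to_best), 0.7)
})

test_that("the slope stage is skipped when the within effect is not significant", {
  x <- generate_dataset(synthetic_config(seed = 10))  # no env effects
  fr <- prepare_env_model_frame(x$dataset, "red_blood_cell", "d15N", "SAM")
  gate <- test_within_effect_then_slopes(fr, "d15N", "SAM_within",
                                         "SAM_between")
  expect_false(gate$within_significant)
  expect_false(gate$slope_evaluated)
  expect_true(is.na(gate$p_slope))
})

test_that("trait model tables carry null row and effect tests", {
  cfg <- synthetic_config(seed = 17,
                          trait_link = list(beta_within = 0.5,
                                            beta_between = 0.5,
                                            isotope = "d15N"))
  x <- generate_dataset(cfg)
  tab <- build_trait_model_set(x$dataset, "body_mass")
  expect_equal(nrow(tab), 3)  # null + d15N + d13C covariate models
  expect_true("Null" %in% tab$model)
  expect_equal(tab$delta_aic[1], 0)
  tests <- attr(tab, "effect_tests")
  expect_equal(nrow(tests), 2)
  expect_true(all(c("p_within", "p_between") %in% names(tests)))
  expect_true(all(tests$p_within >= 0 & tests$p_within <= 1))
})

test_that("an among-individual-only trait link is attributed to the between effect", {
  hits <- t(vapply(1:100, function(seed) {
    cfg <- synthetic_config(
      seed = 4000 + seed,
      trait_link = list(beta_within = 0, beta_between = 0.8,
                        isotope = "d15N"),
      trait_variances = list(individual = 0.05, year = 0.25,
                             residual = 0.45)
    )
    x <- generate_dataset(cfg)
    fr <- prepare_trait_model_frame(x$dataset, "body_mass", "d15N")
    full <- fit_lmm(fr, lmm_spec("body_mass",
                                 c("d15N_within", "d15N_between"),
                                 method = "ML"))
    no_b <- fit_lmm(fr, lmm_spec("body_mass", "d15N_within",
                                 method = "ML"))
    no_w <- fit_lmm(fr, lmm_spec("body_mass", "d15N_between",
                                 method = "ML"))
    c(between = lrt_pvalue(full$loglik, no_b$loglik, 1) < 0.05,
      within = lrt_pvalue(full$loglik, no_w$loglik, 1) < 0.05)
  }, logical(2)))
  expect_gte(mean(hits[, "between"]), 0.8)   # real effect detected
  expect_lte(mean(hits[, "within"]), 0.2)    # absent effect mostly quiet
})

test_that("trait-effect inference is invariant to positive trait rescaling", {
  x <- generate_dataset(synthetic_config(seed = 23))
  fr <- prepare_trait_model_frame(x$dataset, "total_clutch_mass", "d13C")
  p1 <- test_within_effect_then_slopes(fr, "total_clutch_mass",
                                       "d13C_within", "d13C_between")
  ds2 <- x$dataset
  ds2$traits <- ds2$traits |>
    dplyr::mutate(a_egg_mass = 3 * a_egg_mass,
                  b_egg_mass = 3 * b_egg_mass,
                  total_clutch_mass = 3 * total_clutch_mass)
  fr2 <- prepare_trait_model_frame(ds2, "total_clutch_mass", "d13C")
  p2 <- test_within_effect_then_slopes(fr2, "total_clutch_mass",
                                       "d13C_within", "d13C_between")
  expect_equal(p1$p_within, p2$p_within, tolerance = 1e-6)
})

test_that("failed fits are recorded per row, not fatal", {
  x <- generate_dataset(synthetic_config(seed = 3))
  ds <- x$dataset
  # corrupt one env series so its window means are missing
  ds$env <- dplyr::filter(ds$env, !(index_name == "SOI" & month == 8))
  expect_error(
    build_environment_model_set(ds, "red_blood_cell", "d15N",
                                env_names = c("SAM", "SOI")),
    class = "iso_missing_env"
  )
  # a fit-level failure inside one model is recorded in its row: force it
  # with a covariate that is collinear with the intercept
  fr <- prepare_env_model_frame(ds, "red_blood_cell", "d15N", "SAM")
  fr$degenerate <- 1
  row <- isoniche:::fit_comparison_row(fr, "d15N", "bad", "degenerate")
  expect_true(is.na(row$row$akaike_ic))
  expect_type(row$row$error, "character")
  expect_false(is.na(row$row$error))
})
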