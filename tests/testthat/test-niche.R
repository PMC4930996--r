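test_that("WIC and AIC match hand arithmetic under both conventions", {
  # A = {10, 12}, B = {11, 13, 15}
  samples <- make_samples(list(A = c(10, 12), B = c(11, 13, 15)))

  # population (n): mean(1, 8/3); sample (n-1): mean(2, 4)
  expect_equal(
    within_individual_component(samples, "red_blood_cell", "d15N",
                                "population"),
    mean(c(1, 8 / 3)), tolerance = 1e-12
  )
  expect_equal(
    within_individual_component(samples, "red_blood_cell", "d15N",
                                "sample"),
    3.0, tolerance = 1e-12
  )

  # individual means {11, 13}
  expect_equal(
    among_individual_component(samples, "red_blood_cell", "d15N",
                               "population"),
    1.0, tolerance = 1e-12
  )
  expect_equal(
    among_individual_component(samples, "red_blood_cell", "d15N",
                               "sample"),
    2.0, tolerance = 1e-12
  )
  expect_equal(total_niche_width(mean(c(1, 8 / 3)), 1.0),
               mean(c(1, 8 / 3)) + 1, tolerance = 1e-12)
})

test_that("degenerate and boundary niche cases behave as defined", {
  # identical repeated values -> WIC 0; equal means -> AIC 0
  flat <- make_samples(list(A = c(10, 10, 10), B = c(12, 12)))
  expect_equal(within_individual_component(flat, "red_blood_cell", "d15N"),
               0)
  same_mean <- make_samples(list(A = c(10, 14), B = c(11, 13)))
  expect_equal(among_individual_component(same_mean, "red_blood_cell",
                                          "d15N"), 0)

  expect_equal(total_niche_width(0, 0), 0)
  expect_error(total_niche_width(-0.1, 0.5))
  expect_error(specialization_ratio(0.2, 0))
  expect_equal(specialization_ratio(0.5, 0.5), 1)  # true generalist

  # individuals with a single sample drop from WIC with a warning,
  # or error on request
  single <- make_samples(list(A = c(10, 12), B = 11))
  expect_warning(
    w <- within_individual_component(single, "red_blood_cell", "d15N"),
    class = "iso_few_samples_warning"
  )
  expect_equal(w, 1)  # population variance of {10, 12}
  expect_error(
    within_individual_component(single, "red_blood_cell", "d15N",
                                on_few = "error"),
    class = "iso_few_samples_error"
  )
  expect_error(
    among_individual_component(make_samples(list(A = c(10, 12))),
                               "red_blood_cell", "d15N"),
    class = "iso_too_few_individuals"
  )
})

test_that("brute-force oracle: components equal direct variance formulas", {
  set.seed(101)
  for (n_ind in 2:5) {
    for (n_rep in 2:5) {
      vals <- lapply(seq_len(n_ind), function(i) rnorm(n_rep, 12, 1))
      names(vals) <- sprintf("I%02d", seq_len(n_ind))
      samples <- make_samples(vals)
      mat <- do.call(rbind, vals)
      pvar <- function(x) mean((x - mean(x))^2)
      expect_equal(
        within_individual_component(samples, "red_blood_cell", "d15N",
                                    "population"),
        mean(apply(mat, 1, pvar)), tolerance = 1e-12
      )
      expect_equal(
        among_individual_component(samples, "red_blood_cell", "d15N",
                                   "population"),
        pvar(rowMeans(mat)), tolerance = 1e-12
      )
      expect_equal(
        within_individual_component(samples, "red_blood_cell", "d15N",
                                    "sample"),
        mean(apply(mat, 1, var)), tolerance = 1e-12
      )
      expect_equal(
        among_individual_component(samples, "red_blood_cell", "d15N",
                                   "sample"),
        var(rowMeans(mat)), tolerance = 1e-12
      )
    }
  }
})

test_that("scale equivariance: c^2 on components, ratio invariant", {
  set.seed(7)
  vals <- lapply(1:6, function(i) rnorm(4, 12, 1))
  names(vals) <- sprintf("I%02d", 1:6)
  samples <- make_samples(vals)
  scaled <- samples
  cc <- 3.7
  scaled$d15N <- scaled$d15N * cc
  nd <- niche_decomposition(samples, tissues = "red_blood_cell",
                            isotopes = "d15N")
  nds <- niche_decomposition(scaled, tissues = "red_blood_cell",
                             isotopes = "d15N")
  expect_equal(nds$wic, nd$wic * cc^2, tolerance = 1e-10)
  expect_equal(nds$aic_niche, nd$aic_niche * cc^2, tolerance = 1e-10)
  expect_equal(nds$tnw, nd$tnw * cc^2, tolerance = 1e-10)
  expect_equal(nds$ratio, nd$ratio, tolerance = 1e-12)
  # decomposition identity holds by construction
  expect_equal(nd$tnw, nd$wic + nd$aic_niche, tolerance = 1e-15)
})

test_that("ratio decreases as among-individual spread grows", {
  set.seed(42)
  base <- lapply(1:10, function(i) rnorm(4, 0, 1))
  ratios <- vapply(c(0, 0.5, 1, 2, 4), function(spread) {
    # hold within-individual spread fixed (centered draws) and move the
    # individual means apart deterministically
    vals <- lapply(seq_along(base), function(i) {
      base[[i]] - mean(base[[i]]) +
        spread * qnorm((i - 0.5) / length(base))
    })
    names(vals) <- sprintf("I%02d", seq_along(vals))
    nd <- niche_decomposition(make_samples(vals),
                              tissues = "red_blood_cell",
                              isotopes = "d15N")
    nd$ratio
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("niche table writer prints half-up 2-decimal values", {
  samples <- make_samples(list(A = c(10, 12), B = c(11, 13, 15)),
                          values13 = list(A = c(-19, -18.5),
                                          B = c(-18.8, -18.6, -18.2)))
  feather <- make_samples(list(A = c(13, 14), B = c(13.5, 14.5)),
                          tissue = "feather")
  nd <- niche_decomposition(dplyr::bind_rows(samples, feather))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_niche_table(nd, path)
  lines <- readLines(path)
  expect_length(lines, 7)  # header + 4 quantities + 2 footer rows
  expect_match(lines[1], "^quantity\t")
  expect_match(lines[5], "^WIC/TNW\t")
  # the half-up rule itself
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(0.6785714, 2), 0.68)
})
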