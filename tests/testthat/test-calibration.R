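test_that("exact linear training data is recovered perfectly", {
  lg <- c(-2, -1, 0, 1, 2)
  recs <- data.frame(nades_id = paste0("n", 1:5), ln_gamma = lg,
                     s_exp = 2 * lg + 5)
  cal <- fit_calibration(recs)
  expect_equal(unname(coef(cal)), c(5, 2), tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(predict(cal, ln_gamma = 0.5)), 6, tolerance = 1e-12)
  expect_equal(unname(residuals(cal)), rep(0, 5), tolerance = 1e-10)
})

test_that("noisy synthetic training recovers the generating line within its CI", {
  tr <- make_training_set(n = 15, seed = 2024)
  truth <- attr(tr, "truth")
  recs <- data.frame(nades_id = tr$nades_id, s_exp = tr$s_exp,
                     ln_gamma = tr$ln_gamma)
  cal <- fit_calibration(recs)
  ci <- confint(cal)
  expect_gte(truth$slope, ci["slope", 1])
  expect_lte(truth$slope, ci["slope", 2])
  expect_gte(truth$intercept, ci["intercept", 1])
  expect_lte(truth$intercept, ci["intercept", 2])
  expect_gt(cal$r_squared, 0.9)
})

test_that("degenerate calibration inputs are rejected", {
  recs <- data.frame(nades_id = c("a", "b", "c"), s_exp = c(1, 2, 3),
                     ln_gamma = c(1, 1, 1))
  expect_error(fit_calibration(recs), "degenerate")
  expect_error(fit_calibration(recs[1:2, ]), "at least 3")
  recs$ln_gamma <- c(1, 2, 3); recs$s_exp <- c(1, -2, 3)
  expect_error(fit_calibration(recs), "> 0")
})

test_that("the log-form calibration back-transforms predictions", {
  lg <- seq(-3, 1, length.out = 8)
  recs <- data.frame(nades_id = paste0("n", 1:8), ln_gamma = lg,
                     s_exp = exp(-0.8 * lg + 0.2))
  cal <- fit_calibration(recs, form = "log")
  expect_equal(unname(coef(cal)), c(0.2, -0.8), tolerance = 1e-10)
  expect_equal(unname(predict(cal, ln_gamma = -1)), exp(1.0), tolerance = 1e-8)
})

test_that("screening rows reproduce the reported percent and fold arithmetic", {
  # identity calibration: candidates are predicted solubilities directly
  recs <- data.frame(nades_id = paste0("t", 1:3), ln_gamma = c(1, 2, 3),
                     s_exp = c(1, 2, 3))
  ident <- fit_calibration(recs)
  scr <- predict_and_rank(ident, c(best = 5.25, good = 4.21, ok = 4.06),
                          s_ref = 2.26, s_water = 0.120)
  expect_identical(scr$nades_id, c("best", "good", "ok"))  # sorted descending
  expect_identical(scr$pct_increase_vs_ref[scr$nades_id == "good"], 86L)
  expect_identical(scr$pct_increase_vs_ref[scr$nades_id == "ok"], 80L)
  expect_identical(scr$fold_vs_water[scr$nades_id == "ok"], 34L)
  expect_identical(scr$fold_vs_water[scr$nades_id == "best"], 44L)
  # zero increase at the reference solubility
  at_ref <- predict_and_rank(ident, c(ref = 2.26), s_ref = 2.26, s_water = 0.12)
  expect_identical(at_ref$pct_increase_vs_ref, 0L)
  # derived quantities recompute from s_pred exactly
  expect_identical(scr$pct_increase_vs_ref,
                   as.integer(round(100 * (scr$s_pred - 2.26) / 2.26)))
  expect_identical(scr$fold_vs_water, as.integer(round(scr$s_pred / 0.120)))
})

test_that("ranking is invariant under a consistent positive recalibration", {
  cand <- c(a = -3.2, b = -1.1, c = 0.4, d = 2.2)
  recs1 <- data.frame(nades_id = paste0("t", 1:3), ln_gamma = c(-2, 0, 2),
                      s_exp = c(5, 3, 1))
  recs2 <- data.frame(nades_id = paste0("t", 1:3), ln_gamma = c(-2, 0, 2),
                      s_exp = c(11, 6.2, 1.4))  # different slope, same sign
  r1 <- predict_and_rank(fit_calibration(recs1), cand)
  r2 <- predict_and_rank(fit_calibration(recs2), cand)
  expect_identical(r1$nades_id, r2$nades_id)
})

test_that("relative differences report at one-decimal precision", {
  expect_identical(relative_difference(2.26, 0.0286), 1.3)
  expect_identical(relative_difference(5, 0), 0)
  expect_identical(relative_difference(2.0, 0.5), 25.0)
  expect_error(relative_difference(0, 0.1), "> 0")
})

test_that("substituent-acidity correlation recovers sign and strength", {
  collinear <- data.frame(pka = c(7, 8, 9, 10), s_pred = c(1, 2, 3, 4))
  out <- pka_solubility_correlation(collinear)
  expect_equal(out$pearson_r, 1, tolerance = 1e-12)
  expect_equal(out$slope, 1, tolerance = 1e-12)
  anti <- data.frame(pka = c(7, 8, 9, 10), s_pred = c(4, 3.1, 2.2, 0.9))
  expect_lt(pka_solubility_correlation(anti)$pearson_r, 0)
  set.seed(99)
  pka <- runif(20, 6, 12)
  noisy <- data.frame(pka = pka, s_pred = 0.4 * pka + rnorm(20, 0, 0.3))
  fitn <- pka_solubility_correlation(noisy)
  expect_gt(fitn$pearson_r, 0)
  se <- 0.3 / (sd(pka) * sqrt(19))
  expect_lt(abs(fitn$slope - 0.4), 2.6 * se)
  expect_error(pka_solubility_correlation(data.frame(pka = c(7, 7, 7),
                                                     s_pred = 1:3)), "equal")
})
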