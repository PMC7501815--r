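g <- example_genotype()
k <- species_constants()

test_that("noise-free tip counts give back the phyllochron exactly", {
  sim <- simulate_plant(g, benign_env(60, vpd = 0, psi = 0))
  obs <- generate_observations(sim, timing_sd = 0, dim_cv = 0,
                               n_plants = 1, seed = 1)
  tip <- fit_stage_regression(obs$stage_counts, "tip")
  expect_equal(tip$slope, g$a_tip, tolerance = 1e-9)
  expect_equal(tip$intercept, g$b_tip, tolerance = 1e-9)
  # ligule events are interval-censored on the 2-day scoring grid, so the
  # noise-free estimate is only guaranteed to half the scoring interval
  lig <- fit_stage_regression(obs$stage_counts, "ligule", g$n_final)
  expect_lt(abs(lig$slope - g$a_ll1), 2)
  expect_lt(abs(lig$intercept - g$b_ll1), 20)
  few <- obs$stage_counts[obs$stage_counts$day <= 2, ]
  expect_error(fit_stage_regression(few, "tip"), "insufficient")
})

test_that("stage regressions are unbiased under scoring-time noise", {
  sim <- simulate_plant(g, benign_env(60, vpd = 0, psi = 0))
  reps <- vapply(1:60, function(s) {
    obs <- generate_observations(sim, timing_sd = 10, dim_cv = 0, seed = s)
    tip <- fit_stage_regression(obs$stage_counts, "tip")
    lig <- fit_stage_regression(obs$stage_counts, "ligule", g$n_final)
    c(tip$slope, tip$intercept, lig$slope, lig$intercept)
  }, numeric(4))
  m <- rowMeans(reps)
  expect_equal(m[1], 40, tolerance = 0.02)
  expect_equal(m[2], 20, tolerance = 0.05)
  expect_equal(m[3], 60, tolerance = 0.02)
  expect_equal(m[4], 100, tolerance = 0.05)
})

test_that("the growth window converges to the 5/95% ramp crossings", {
  tt <- seq(0, 700, by = 10)
  ramp <- pmin(pmax(0, (tt - 260) * 2.575), 2.575 * 167.6)
  gw <- extract_growth_window(tt, ramp, span = 0.1)
  expect_equal(gw$tt_begin, 268.38, tolerance = 1e-2) # 260 + 0.05*167.6
  expect_equal(gw$tt_end, 419.22, tolerance = 1e-2)   # 260 + 0.95*167.6
  # at the documented default span the corners are smoothed: bias bounded
  gw5 <- extract_growth_window(tt, ramp, span = 0.5)
  expect_lt(abs(gw5$tt_begin - 268.38), 20)
  expect_lt(abs(gw5$tt_end - 419.22), 20)
  # thresholds are relative: doubling the amplitude moves nothing
  gw2 <- extract_growth_window(tt, 2 * ramp, span = 0.1)
  expect_equal(c(gw2$tt_begin, gw2$tt_end), c(gw$tt_begin, gw$tt_end),
               tolerance = 1e-9)
})

test_that("curves without a plateau are rejected", {
  tt <- seq(0, 700, by = 10)
  expect_error(extract_growth_window(tt, rep(0, length(tt)), span = 0.2),
               "plateau")
  expect_error(extract_growth_window(tt, 1.2 * tt, span = 0.2), "plateau")
  expect_error(extract_growth_window(tt[1:5], tt[1:5]), "10 observations")
})

test_that("the leaf-6 slope is read off the linear phase", {
  tt <- seq(0, 700, by = 10)
  ramp <- pmin(pmax(0, (tt - 260) * 2.575), 2.575 * 167.6)
  est <- estimate_max_ler6(tt, ramp, c(270, 410))
  expect_equal(est$a6, 2.575, tolerance = 1e-12)
  expect_error(estimate_max_ler6(tt, ramp, c(800, 900)), "fewer than 3")
  expect_error(estimate_max_ler6(tt, ramp, c(410, 270)), "window")
  # a window lying wholly in the plateau is caught by the value guard
  expect_error(estimate_max_ler6(tt, ramp, c(500, 700),
                                 value_range = c(0.05, 0.95) * 431.57),
               "fewer than 3")
})

test_that("soil-water sensitivity is fitted with the intercept pinned at 1", {
  psi <- seq(-0.6, -0.05, length.out = 12)
  expect_equal(estimate_psi_sensitivity(1 + 0.5 * psi, psi,
                                        rate_ww = 1)$c_rel, 0.5,
               tolerance = 1e-12)
  # an explicit well-watered rate rescales exactly
  expect_equal(estimate_psi_sensitivity(3 * (1 + 0.8 * psi), psi,
                                        rate_ww = 3)$c_rel, 0.8,
               tolerance = 1e-12)
  # self-normalisation uses records at slightly negative psi as the
  # well-watered baseline, so it is only approximately unbiased
  est <- estimate_psi_sensitivity(3 * (1 + 0.8 * psi), psi)
  expect_equal(est$c_rel, 0.8, tolerance = 0.1)
  expect_error(estimate_psi_sensitivity(rep(1, 5), rep(-0.3, 5)),
               "range")
})

test_that("noisy drydown records recover the sensitivity on average", {
  psi <- rep(seq(-0.6, -0.05, length.out = 10), each = 5)
  cs <- vapply(1:100, function(s) {
    set.seed(s)
    rate <- 1 + 0.5 * psi + rnorm(length(psi), sd = 0.05)
    estimate_psi_sensitivity(rate, psi, rate_ww = 1)$c_rel
  }, numeric(1))
  expect_equal(mean(cs), 0.5, tolerance = 0.05)
})

test_that("the demand sensitivity follows from the soil-water one", {
  expect_equal(b_from_c(0), 0.69)
  expect_equal(b_from_c(0.3), 0)
  expect_equal(b_from_c(1), -1.61)
  # affine: equal increments in c give equal decrements in b
  expect_equal(diff(b_from_c(c(0.1, 0.2, 0.3))), rep(-0.23, 2))
})

test_that("relative sensitivities scale to the absolute rate model by a6", {
  ab <- to_absolute_sensitivities(-0.46, 0.5, 5)
  expect_equal(ab$b, -2.3)
  expect_equal(ab$c, 2.5)
  expect_equal(to_absolute_sensitivities(-0.2, 0.7, 1),
               list(b = -0.2, c = 0.7))
  expect_equal(to_absolute_sensitivities(-0.2, 0, 5)$c, 0)
  expect_error(to_absolute_sensitivities(-0.2, 0.5, -1), "a6")
})

test_that("widening sensitivity and reference width come from the light gradient", {
  rad <- c(0.6, 0.9, 1.2, 1.5, 1.8)
  width <- 55 + 10 * rad
  est <- estimate_rad_sensitivity(width, rad)
  expect_equal(est$r_rad, 10, tolerance = 1e-9)
  expect_error(estimate_rad_sensitivity(width[1:3], rep(1, 3)),
               "single light level")
  expect_equal(normalize_w6(67, 1.5, 10), 67)
  expect_equal(normalize_w6(67, 1.0, 10), 72)
})

test_that("flowering-time cross-validation measures honest prediction error", {
  nf <- rep(12:25, each = 4)
  tt_flo <- 30 * nf + 400
  expect_equal(kfold_rmse(nf, tt_flo, folds = 5, seed = 2)$rmse, 0,
               tolerance = 1e-9)
  # with pure Gaussian noise the held-out RMSE approaches the noise sd
  set.seed(11)
  nf_big <- rep(12:25, each = 30)
  noisy <- 30 * nf_big + 400 + rnorm(length(nf_big), sd = 50)
  cvres <- kfold_rmse(nf_big, noisy, folds = 5, seed = 3)
  expect_equal(cvres$rmse, 50, tolerance = 0.1)
  expect_equal(cvres$cv_pct, 100 * cvres$rmse / mean(noisy))
  expect_error(kfold_rmse(nf[1:8], tt_flo[1:8], folds = 5), "folds")
  # seeded partition: reproducible
  expect_identical(kfold_rmse(nf, tt_flo + 1, folds = 5, seed = 7),
                   kfold_rmse(nf, tt_flo + 1, folds = 5, seed = 7))
})

test_that("calibration is invariant to record ordering", {
  psi <- seq(-0.6, -0.05, length.out = 12)
  rate <- 1 + 0.37 * psi
  perm <- sample(seq_along(psi))
  expect_equal(estimate_psi_sensitivity(rate, psi, rate_ww = 1)$c_rel,
               estimate_psi_sensitivity(rate[perm], psi[perm],
                                        rate_ww = 1)$c_rel,
               tolerance = 1e-12)
})

test_that("the full observation-to-parameter round trip closes", {
  sim <- simulate_plant(g, benign_env(60, vpd = 0, psi = 0))
  obs0 <- generate_observations(sim, timing_sd = 0, dim_cv = 0,
                                n_plants = 1, seed = 1)
  cal0 <- calibrate_genotype(obs0, g$n_final)
  est0 <- cal0$estimates
  expect_equal(est0[["a_tip"]], 40, tolerance = 1e-6)
  expect_equal(est0[["b_tip"]], 20, tolerance = 1e-6)
  expect_equal(est0[["a6"]], 5, tolerance = 1e-6)
  expect_lt(abs(est0[["a_ll1"]] - 60), 2)    # interval censoring bound
  expect_lt(abs(est0[["b_ll1"]] - 100), 20)
  # default-noise replicates: see the acceptance suite for the full run
  ests <- vapply(1:20, function(s)
    calibrate_genotype(generate_observations(sim, seed = s),
                       g$n_final)$estimates, numeric(5))
  truth <- c(a_tip = 40, b_tip = 20, a_ll1 = 60, b_ll1 = 100, a6 = 5)
  expect_true(all(abs(rowMeans(ests) - truth) / truth < 0.05))
})
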