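g <- example_genotype()
k <- species_constants()
sched <- build_schedule(g)

test_that("the rank bell is normalised to 1 at leaf 6", {
  for (nf in c(8, 12, 16, 20, 30))
    expect_equal(normalized_ler(6, nf), 1, tolerance = 1e-12)
  # peak value at the continuous maximum B_L = 10.88 equals theta_L
  expect_equal(normalized_ler(10.88, 16, allow_real = TRUE), 1.245844,
               tolerance = 1e-6)
  expect_equal(normalized_ler(16, 16), 0.9780909, tolerance = 1e-6)
  expect_error(normalized_ler(17, 16), "rank")
})

test_that("the daily increment combines bell, stress response and thermal time", {
  # day fully inside leaf 6's elongation window, dtt = 15
  env <- environment_series(0:29, temperature = 23, vpd = 1, psi = -0.2,
                            rad = 1)
  day_in <- env[env$tt0 >= 260 & env$tt1 <= 427.6, ][1, ]
  expect_equal(instantaneous_ler(6, day_in, sched, g),
               (5 - 2.3 * 1 + 2.5 * -0.2) * 15) # 2.2 mm/Cd * 15 Cd = 33 mm
  # sensitivities zero: the potential rate a6 applies whatever the forcing
  g0 <- genotype_parameters(16, 40, 20, 60, 100, 5, 0, 0, 70, 10)
  expect_equal(instantaneous_ler(6, day_in, sched, g0), 5 * 15)
  # stress below the compensation point is clamped at zero
  env_dry <- environment_series(0:29, temperature = 23, vpd = 3,
                                psi = -2, rad = 1)
  day_dry <- env_dry[env_dry$tt0 >= 260 & env_dry$tt1 <= 427.6, ][1, ]
  expect_equal(instantaneous_ler(6, day_dry, sched, g), 0)
})

test_that("day-stepped integration matches the closed form under constant forcing", {
  env <- benign_env(60)
  len <- integrate_length(6, sched, env, g)
  final <- len$length_mm[nrow(len)]
  expect_equal(final, 431.57, tolerance = 1e-9)
  expect_equal(final, closed_form_length(6, sched, 1, -0.05, g),
               tolerance = 1e-12)
  # every rank, not just the reference leaf
  for (n in c(1, 4, 9, 13, 16))
    expect_equal(integrate_length(n, sched, env, g)$length_mm[60],
                 closed_form_length(n, sched, 1, -0.05, g),
                 tolerance = 1e-9)
})

test_that("length is linear in the stress-free rate and zero without overlap", {
  env <- benign_env(60)
  g_half <- genotype_parameters(16, 40, 20, 60, 100, 2.5,
                                -2.3 / 2, 2.5 / 2, 70, 10)
  l1 <- integrate_length(6, sched, env, g)$length_mm[60]
  l2 <- integrate_length(6, sched, env, g_half)$length_mm[60]
  expect_equal(l2, l1 / 2, tolerance = 1e-12)
  # weather ending before the window opens: zero length, truncation flag
  env_short <- benign_env(10) # 200 Cd < tt_bl(6) = 260
  len <- integrate_length(6, sched, env_short, g)
  expect_equal(len$length_mm, rep(0, 10))
  expect_true(attr(len, "truncated"))
})

test_that("final length responds monotonically to the environment", {
  finals_vpd <- vapply(seq(0, 3, by = 0.5), function(v)
    closed_form_length(8, sched, v, -0.05, g), numeric(1))
  expect_true(all(diff(finals_vpd) <= 0)) # b < 0: drier air, shorter leaf
  finals_psi <- vapply(seq(-1, 0, by = 0.2), function(p)
    closed_form_length(8, sched, 1, p, g), numeric(1))
  expect_true(all(diff(finals_psi) >= 0)) # c > 0: wetter soil, longer leaf
})

test_that("length trajectories are flat outside the elongation window", {
  env <- benign_env(60)
  len <- integrate_length(10, sched, env, g)
  row <- sched[sched$rank == 10, ]
  before <- len$tt1 < row$tt_bl
  after <- len$tt1 > row$tt_el
  expect_true(all(len$length_mm[before] == 0))
  expect_equal(len$length_mm[after],
               rep(len$length_mm[60], sum(after)), tolerance = 1e-12)
  expect_true(all(diff(len$length_mm) >= 0))
})
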