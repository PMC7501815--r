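# Event-time equations checked against hand-evaluated values for the
# worked-example genotype: n_final 16, a_tip 40, b_tip 20, a_ll1 60,
# b_ll1 100, default species constants.

g <- example_genotype()
k <- species_constants()

test_that("tip appearance is linear in rank", {
  expect_equal(tt_tip(1, g), 60)
  expect_equal(tt_tip(6, g), 260)
  expect_error(tt_tip(0, g), "rank")
  expect_error(tt_tip(17, g), "rank")
})

test_that("beginning of linear elongation branches at rank 6 continuously", {
  expect_equal(tt_begin_linear(6, g), tt_tip(6, g))
  expect_equal(tt_begin_linear(1:6, g), tt_tip(1:6, g))
  # hand value for rank 7 with k_bl = 0.708: 0.708*40*7 + 20 + 240*0.292
  expect_equal(tt_begin_linear(7, g), 288.32, tolerance = 1e-12)
  # the upper-branch formula evaluated at the breakpoint gives the same value
  b_bl <- g$b_tip + k$n_bl_lim * g$a_tip * (1 - k$k_bl)
  expect_equal(k$k_bl * g$a_tip * 6 + b_bl, tt_tip(6, g),
               tolerance = 1e-12)
})

test_that("ligule appearance is a continuous two-segment line", {
  # breakpoint at 0.52 * 16 = 8.32: rank 8 on the first segment
  expect_equal(tt_ligule(8, g), 580)
  # rank 9 on the second: slope 0.454*60 = 27.24, intercept 372.5632
  expect_equal(tt_ligule(9, g), 617.7232, tolerance = 1e-12)
  # both branch formulas agree at the real-valued breakpoint
  n_star <- k$alpha_ll * g$n_final
  b_ll2 <- g$b_ll1 + g$a_ll1 * n_star * (1 - k$k_ll)
  expect_equal(g$a_ll1 * n_star + g$b_ll1,
               k$k_ll * g$a_ll1 * n_star + b_ll2, tolerance = 1e-9)
})

test_that("end of linear elongation lags ligulation and ties the top ranks", {
  expect_equal(tt_end_linear(10, g), 590.9632, tolerance = 1e-12)
  expect_equal(tt_end_linear(16, g), tt_end_linear(15, g))
  expect_equal(tt_end_linear(15, g), 700.1632, tolerance = 1e-12)
  sched <- build_schedule(g)
  expect_equal(length(unique(sched$tt_el)), g$n_final - 1L)
  below_cap <- sched$rank <= g$n_final - k$n_last + 1
  expect_equal((sched$tt_ll - sched$tt_el)[below_cap],
               k$a_lag * sched$rank[below_cap])
})

test_that("the widening window ends 39 degree-days before elongation does", {
  w <- widening_window(10, g)
  expect_equal(w$tt_beg_w, 373.28, tolerance = 1e-12)
  expect_equal(w$tt_end_w, 551.9632, tolerance = 1e-12)
  sched <- build_schedule(g)
  expect_equal(sched$tt_el - sched$tt_end_w, rep(39, g$n_final))
  # a pathological lag makes the window empty for early ranks
  expect_error(widening_window(1, g, species_constants(lag_w = 500)),
               "inconsistent schedule")
})

test_that("the full schedule is internally consistent", {
  sched <- build_schedule(g)
  expect_equal(nrow(sched), 16L)
  n <- sched$rank
  expect_equal(sched$tt_tip, tt_tip(n, g))
  expect_equal(sched$tt_bl, tt_begin_linear(n, g))
  expect_equal(sched$tt_ll, tt_ligule(n, g))
  expect_equal(sched$tt_el, tt_end_linear(n, g))
  # event ordering invariants
  expect_true(all(sched$tt_bl <= sched$tt_tip))
  expect_true(all(sched$tt_bl[n <= 6] == sched$tt_tip[n <= 6]))
  expect_true(all(sched$tt_bl < sched$tt_el))
  expect_true(all(sched$tt_el < sched$tt_ll))
  expect_true(all(diff(sched$tt_tip) > 0))
  expect_true(all(diff(sched$tt_bl) > 0))
  expect_true(all(diff(sched$tt_ll) > 0))
})

test_that("schedules exist for the smallest admissible plant", {
  g8 <- genotype_parameters(8, 40, 20, 60, 100, 5, -2.3, 2.5, 70, 10)
  sched <- build_schedule(g8)
  expect_equal(nrow(sched), 8L)
  expect_error(genotype_parameters(7, 40, 20, 60, 100, 5, -2.3, 2.5, 70, 10),
               "n_final")
})

test_that("stage regressions on noise-free schedules recover the slope ratios", {
  sched <- build_schedule(g)
  upper <- sched$rank >= 7
  fit_bl <- lm(tt_bl ~ rank, data = sched[upper, ])
  expect_equal(unname(coef(fit_bl)[2]) / g$a_tip, k$k_bl, tolerance = 1e-9)
  pre <- sched$rank <= 8; post <- sched$rank >= 9
  s_pre <- unname(coef(lm(tt_ll ~ rank, data = sched[pre, ]))[2])
  s_post <- unname(coef(lm(tt_ll ~ rank, data = sched[post, ]))[2])
  expect_equal(s_post / s_pre, k$k_ll, tolerance = 1e-9)
})
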