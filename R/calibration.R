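# Calibration of the genotypic parameters from longitudinal observations:
# stage-count regressions for the event-timing parameters, dissection time
# courses for the elongation parameters, platform drydowns for the drought
# and demand sensitivities, and width-versus-light regressions for the
# widening parameters.

# Thermal times at which an integer count series crossed each new value.
# Counts are interval-censored (scored every few days); the crossing of
# level k is placed where the linear interpolant of the counts passes
# k - 1/2, the midpoint convention for an event uniformly located between
# the bracketing scoring dates.
stage_event_times <- function(tt, count) {
  o <- order(tt)
  tt <- tt[o]; count <- count[o]
  if (any(diff(count) < 0))
    stop("stage counts must be non-decreasing in thermal time",
         call. = FALSE)
  ranks <- numeric(0); times <- numeric(0)
  for (i in seq_along(tt)[-1L]) {
    c0 <- count[i - 1L]; c1 <- count[i]
    if (c1 > c0) {
      ks <- seq.int(c0 + 1L, c1)
      times <- c(times, tt[i - 1L] +
                   (ks - 0.5 - c0) / (c1 - c0) * (tt[i] - tt[i - 1L]))
      ranks <- c(ranks, ks)
    }
  }
  data.frame(rank = ranks, tt = times)
}

#' Fit the stage regression for tip or ligule appearance
#'
#' Estimates the slope and intercept of thermal time against leaf rank from
#' scored counts of appeared tips (giving `a_tip`, `b_tip`) or ligulated
#' leaves (giving `a_ll1`, `b_ll1`). Counts are converted to per-rank event
#' times (the thermal time at which the count reached each new value,
#' interpolated between the bracketing scoring dates with the midpoint
#' convention) and pooled across plants; ordinary least squares is then
#' fitted on event time versus rank. For the ligule stage, only ranks at or
#' below the ligulation breakpoint `alpha_ll * n_final` are used when
#' `n_final` is supplied, since the regression parameterises the
#' pre-breakpoint segment.
#'
#' @param stage_counts Data frame with columns `tt` (thermal time of the
#'   scoring date, degree-days) and the counts: either a generic `count`
#'   column, or the [generate_observations()] columns `n_tip` / `n_ligule`
#'   (the one matching `stage` is used). An optional `plant` column
#'   separates replicate plants.
#' @param stage `"tip"` or `"ligule"`.
#' @param n_final Final leaf number, needed to restrict ligule counts to the
#'   pre-breakpoint ranks.
#' @param k A [species_constants()] object.
#' @return A list: `slope` (degree-days per leaf), `intercept`
#'   (degree-days), standard errors, `r_squared`, `n_events`, and the pooled
#'   per-rank event times in `events`.
#' @export
fit_stage_regression <- function(stage_counts,
                                 stage = c("tip", "ligule"),
                                 n_final = NULL,
                                 k = species_constants()) {
  stage <- match.arg(stage)
  if (!("count" %in% names(stage_counts))) {
    alias <- if (stage == "tip") "n_tip" else "n_ligule"
    if (alias %in% names(stage_counts))
      stage_counts$count <- stage_counts[[alias]]
  }
  if (!all(c("tt", "count") %in% names(stage_counts)))
    stop("'stage_counts' needs columns 'tt' and 'count' (or 'n_tip'/'n_ligule')",
         call. = FALSE)
  if (length(unique(stage_counts$tt)) < 3L)
    stop("insufficient data: at least 3 observation dates are required",
         call. = FALSE)
  if (is.null(stage_counts$plant)) stage_counts$plant <- 1L
  ev <- do.call(rbind, lapply(split(stage_counts, stage_counts$plant),
                              function(d) stage_event_times(d$tt, d$count)))
  if (stage == "ligule" && !is.null(n_final))
    ev <- ev[ev$rank <= k$alpha_ll * n_final, ]
  if (nrow(ev) < 3L)
    stop("insufficient data: fewer than 3 stage events observed",
         call. = FALSE)
  fit <- stats::lm(tt ~ rank, data = ev)
  cf <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  list(slope = unname(cf["rank"]), intercept = unname(cf["(Intercept)"]),
       slope_se = unname(se["rank"]), intercept_se = unname(se["(Intercept)"]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n_events = nrow(ev), events = ev)
}

#' Growth window of a dimension time course
#'
#' Smooths a leaf length (or width) time course with local polynomial
#' regression (`stats::loess`) and returns the thermal times at which the
#' smoothed curve first crosses 5% and 95% of its final (plateau) value —
#' the operational beginning and end of linear growth.
#'
#' The plateau is the mean of the smoothed values over the trailing
#' `plateau_frac` of the observations; it must be positive and vary by less
#' than `plateau_tol` (relative) over that stretch, otherwise the curve is
#' judged not to have reached its final dimension. Because the smoother has
#' inflated variance at the series boundary, the variation allowance is
#' widened by three residual standard deviations of the fit: measurement
#' noise alone then cannot trigger the no-plateau error, while a curve that
#' is still growing systematically over the tail stretch does.
#'
#' @param tt Thermal times of the observations (degree-days), increasing.
#' @param value Observed dimension (mm).
#' @param span Loess span; default 0.5.
#' @param plateau_frac Trailing fraction of points defining the plateau.
#' @param plateau_tol Maximum relative variation of the smoothed curve over
#'   the plateau stretch.
#' @param lower,upper Crossing thresholds as fractions of the plateau.
#' @return A list: `tt_begin`, `tt_end` (degree-days), `plateau` (mm), and
#'   the smoothed curve in `smoothed` (data frame `tt`, `fitted`).
#' @export
extract_growth_window <- function(tt, value, span = 0.5,
                                  plateau_frac = 0.1, plateau_tol = 0.05,
                                  lower = 0.05, upper = 0.95) {
  o <- order(tt)
  tt <- tt[o]; value <- value[o]
  if (length(tt) < 10L)
    stop("at least 10 observations are required", call. = FALSE)
  fit <- stats::loess(value ~ tt, span = span, degree = 2,
                      family = "gaussian")
  sm <- stats::fitted(fit)
  n_tail <- max(2L, ceiling(plateau_frac * length(tt)))
  tail_vals <- sm[(length(sm) - n_tail + 1L):length(sm)]
  plateau <- mean(tail_vals)
  allow <- plateau_tol * abs(plateau) + 3 * stats::sd(stats::residuals(fit))
  if (!is.finite(plateau) || plateau <= 0 ||
      (max(tail_vals) - min(tail_vals)) > allow)
    stop("no plateau: the time course has not reached a stable final value",
         call. = FALSE)
  cross <- function(th) {
    y <- sm - th * plateau
    i <- which(y >= 0)[1L]
    if (is.na(i)) stop("smoothed curve never reaches ", th * 100,
                       "% of the plateau", call. = FALSE)
    if (i == 1L) return(tt[1L])
    # linear interpolation between the bracketing smoothed points
    tt[i - 1L] - y[i - 1L] * (tt[i] - tt[i - 1L]) / (y[i] - y[i - 1L])
  }
  list(tt_begin = cross(lower), tt_end = cross(upper), plateau = plateau,
       smoothed = data.frame(tt = tt, fitted = sm))
}

#' Maximum elongation rate of leaf 6 from its length time course
#'
#' Slope of an ordinary least-squares fit of length against thermal time
#' restricted to the linear-growth window (typically the 5-95% window from
#' [extract_growth_window()]), i.e. the genotypic parameter `a6` when the
#' plants are well watered and evaporative demand is negligible.
#'
#' @param tt,value The observed time course (degree-days, mm).
#' @param window Numeric length-2 vector `(tt_begin, tt_end)` delimiting the
#'   linear phase.
#' @param value_range Optional length-2 vector of dimension bounds (mm):
#'   points outside it are excluded even inside the window. Passing the 5%
#'   and 95% plateau fractions guards the slope against corner points when
#'   the window itself is estimated from noisy data.
#' @return A list: `a6` (mm per degree-day), `se`, `n_points`.
#' @export
estimate_max_ler6 <- function(tt, value, window, value_range = NULL) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("'window' must be (tt_begin, tt_end) with tt_begin < tt_end",
         call. = FALSE)
  sel <- tt >= window[1] & tt <= window[2]
  if (!is.null(value_range))
    sel <- sel & value >= value_range[1L] & value <= value_range[2L]
  if (sum(sel) < 3L)
    stop("the window contains fewer than 3 observations", call. = FALSE)
  fit <- stats::lm(value[sel] ~ tt[sel])
  list(a6 = unname(stats::coef(fit)[2L]),
       se = unname(suppressWarnings(sqrt(diag(stats::vcov(fit))))[2L]),
       n_points = sum(sel))
}

#' Soil-water-deficit sensitivity from drydown expansion records
#'
#' Normalises expansion rates by the well-watered rate so that the intercept
#' of the response to soil water potential is 1, and fits the slope of the
#' normalised rate against soil water potential by least squares with the
#' intercept fixed at 1. The returned sensitivity `c_rel` is on the relative
#' scale (per MPa); multiply by `a6` ([to_absolute_sensitivities()]) before
#' use in simulation.
#'
#' @param rate Observed expansion rates (any consistent per-degree-day
#'   unit).
#' @param psi Soil water potential (MPa, <= 0) paired with each rate.
#' @param rate_ww Well-watered reference rate; if `NULL`, the mean rate over
#'   records with `psi >= ww_threshold`.
#' @param ww_threshold Soil water potential above which records count as
#'   well watered (MPa).
#' @param min_range Minimum span of `psi` (MPa) required for a fit.
#' @return A list: `c_rel` (relative sensitivity, per MPa), `rate_ww`,
#'   `n_records`.
#' @export
estimate_psi_sensitivity <- function(rate, psi, rate_ww = NULL,
                                     ww_threshold = -0.1,
                                     min_range = 0.2) {
  if (length(rate) != length(psi))
    stop("'rate' and 'psi' must have the same length", call. = FALSE)
  if (diff(range(psi)) < min_range)
    stop("insufficient soil-water-potential range (need >= ", min_range,
         " MPa)", call. = FALSE)
  if (is.null(rate_ww)) {
    ww <- psi >= ww_threshold
    if (!any(ww))
      stop("no well-watered records (psi >= ", ww_threshold,
           " MPa) to normalise by", call. = FALSE)
    rate_ww <- mean(rate[ww])
  }
  if (rate_ww <= 0) stop("well-watered rate must be positive", call. = FALSE)
  y <- rate / rate_ww
  # least squares of (y - 1) ~ psi with intercept constrained to 1
  c_rel <- sum(psi * (y - 1)) / sum(psi^2)
  list(c_rel = c_rel, rate_ww = rate_ww, n_records = length(rate))
}

#' Evaporative-demand sensitivity from the soil-water sensitivity
#'
#' The sensitivities of elongation to evaporative demand and to soil water
#' deficit are tightly correlated across maize genotypes; the demand
#' sensitivity on the relative scale is obtained from the relative
#' soil-water sensitivity through the empirical linear relation
#' `b_rel = 0.69 - 2.3 * c_rel`.
#'
#' @param c_rel Relative soil-water sensitivity (per MPa), as returned by
#'   [estimate_psi_sensitivity()].
#' @return Relative demand sensitivity `b_rel` (per kPa).
#' @export
b_from_c <- function(c_rel) 0.69 - 2.3 * c_rel

#' Convert relative sensitivities to the absolute scale of the rate model
#'
#' The platform procedures estimate sensitivities on a normalised scale
#' (well-watered rate = 1). The simulator's rate model sums sensitivities
#' with the absolute rate `a6`, so relative values are multiplied by `a6`.
#'
#' @param b_rel,c_rel Relative sensitivities (per kPa, per MPa).
#' @param a6 Maximum elongation rate of leaf 6 (mm per degree-day), > 0.
#' @return A list with absolute `b` (mm per degree-day per kPa) and `c`
#'   (mm per degree-day per MPa).
#' @export
to_absolute_sensitivities <- function(b_rel, c_rel, a6) {
  if (!is.numeric(a6) || a6 <= 0) stop("'a6' must be > 0", call. = FALSE)
  list(b = b_rel * a6, c = c_rel * a6)
}

#' Widening sensitivity to intercepted radiation, and width normalisation
#'
#' `estimate_rad_sensitivity` fits an ordinary least-squares regression of
#' final leaf-6 width on the mean intercepted radiation during each plant's
#' widening window; the slope is the genotypic parameter `r_rad`.
#' `normalize_w6` then reduces an observed width to the reference
#' intercepted radiation (1.5 MJ) to give the genotypic parameter `w6`.
#'
#' @param width Final leaf-6 widths (mm), one per plant.
#' @param rad Mean intercepted radiation during each plant's widening window
#'   (MJ per plant per day).
#' @return For `estimate_rad_sensitivity`, a list: `r_rad` (mm per MJ),
#'   `se`, `intercept`, `r_squared`, `n_plants`.
#' @export
estimate_rad_sensitivity <- function(width, rad) {
  if (length(width) != length(rad) || length(width) < 3L)
    stop("at least 3 paired (width, radiation) records are required",
         call. = FALSE)
  if (length(unique(rad)) < 2L)
    stop("records span a single light level; the slope is not identifiable",
         call. = FALSE)
  fit <- stats::lm(width ~ rad)
  cf <- stats::coef(fit)
  list(r_rad = unname(cf[2L]),
       se = unname(suppressWarnings(sqrt(diag(stats::vcov(fit))))[2L]),
       intercept = unname(cf[1L]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n_plants = length(width))
}

#' @rdname estimate_rad_sensitivity
#' @param width_obs Observed width (mm).
#' @param rad_obs Radiation under which it was observed (MJ).
#' @param r_rad Widening sensitivity (mm per MJ).
#' @param rad_ref Reference radiation (MJ); default 1.5.
#' @export
normalize_w6 <- function(width_obs, rad_obs, r_rad, rad_ref = 1.5) {
  width_obs + r_rad * (rad_ref - rad_obs)
}

#' Regression of flowering time on final leaf number, with k-fold CV
#'
#' `fit_flowering_regression` fits flowering thermal time as a linear
#' function of final leaf number across genotypes. `kfold_rmse` evaluates
#' the predictive accuracy of that regression by k-fold cross-validation
#' with a seeded, size-balanced random partition: each fold is held out in
#' turn, the regression is refitted on the rest, and the root mean square
#' error is computed over all held-out predictions.
#'
#' @param n_final Final leaf numbers (predictor).
#' @param flowering_tt Flowering thermal times (degree-days).
#' @return For `fit_flowering_regression`: a list `slope`, `intercept`,
#'   `r_squared`, `n`. For `kfold_rmse`: a list `rmse` (degree-days),
#'   `cv_pct` (RMSE as % of the mean observed value), `folds`.
#' @export
fit_flowering_regression <- function(n_final, flowering_tt) {
  if (length(n_final) != length(flowering_tt) || length(n_final) < 3L)
    stop("at least 3 paired observations are required", call. = FALSE)
  fit <- stats::lm(flowering_tt ~ n_final)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n = length(n_final))
}

#' @rdname fit_flowering_regression
#' @param folds Number of folds; default 5.
#' @param seed Seed for the random partition.
#' @export
kfold_rmse <- function(n_final, flowering_tt, folds = 5, seed = 1) {
  n <- length(n_final)
  if (length(flowering_tt) != n)
    stop("'n_final' and 'flowering_tt' must have the same length",
         call. = FALSE)
  if (folds < 2 || folds > n / 2)
    stop("'folds' must be between 2 and n/2", call. = FALSE)
  assign_fold <- local({
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    sample(rep_len(seq_len(folds), n)) # size-balanced (+/- 1)
  })
  sq_err <- numeric(n)
  for (f in seq_len(folds)) {
    test <- assign_fold == f
    fit <- stats::lm(flowering_tt[!test] ~ n_final[!test])
    cf <- stats::coef(fit)
    pred <- cf[1L] + cf[2L] * n_final[test]
    sq_err[test] <- (flowering_tt[test] - pred)^2
  }
  rmse <- sqrt(mean(sq_err))
  list(rmse = rmse, cv_pct = 100 * rmse / mean(flowering_tt), folds = folds)
}

#' Estimate the timing and elongation parameters from an observation set
#'
#' Runs the stage-count regressions (tip and ligule) and the leaf-6
#' dissection analysis on one observation set, typically produced by
#' [generate_observations()] or read from equivalent field tables, and
#' returns the five parameters they identify: `a_tip`, `b_tip`, `a_ll1`,
#' `b_ll1` and `a6`. The drought, demand and widening sensitivities need
#' dedicated drydown and light-gradient records and are estimated
#' separately ([estimate_psi_sensitivity()], [b_from_c()],
#' [estimate_rad_sensitivity()]).
#'
#' @param obs A list with `stage_counts` and `dissections` as returned by
#'   [generate_observations()].
#' @param n_final Final leaf number of the genotype (used to restrict the
#'   ligule regression to its pre-breakpoint segment).
#' @param k A [species_constants()] object.
#' @param span Loess span for the leaf-6 growth-window extraction; the
#'   default 0.3 suits series of 25-60 scoring dates spanning a season.
#' @return A list of class `calibration_result`: `estimates` (named vector
#'   `a_tip, b_tip, a_ll1, b_ll1, a6`), `se` (matching standard errors),
#'   and `diagnostics` (the full fit objects of each step).
#' @export
calibrate_genotype <- function(obs, n_final, k = species_constants(),
                               span = 0.3) {
  tip <- fit_stage_regression(obs$stage_counts, "tip", n_final, k)
  lig <- fit_stage_regression(obs$stage_counts, "ligule", n_final, k)
  d6 <- obs$dissections[obs$dissections$rank == 6L, ]
  # dissected plants are destructive replicates: average them per date
  d6 <- stats::aggregate(length_mm ~ tt, data = d6, FUN = mean)
  gw <- extract_growth_window(d6$tt, d6$length_mm, span = span)
  a6 <- estimate_max_ler6(d6$tt, d6$length_mm, c(gw$tt_begin, gw$tt_end),
                          value_range = c(0.05, 0.95) * gw$plateau)
  structure(list(
    estimates = c(a_tip = tip$slope, b_tip = tip$intercept,
                  a_ll1 = lig$slope, b_ll1 = lig$intercept, a6 = a6$a6),
    se = c(a_tip = tip$slope_se, b_tip = tip$intercept_se,
           a_ll1 = lig$slope_se, b_ll1 = lig$intercept_se, a6 = a6$se),
    diagnostics = list(tip = tip, ligule = lig, window = gw, a6 = a6)),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  est <- x$estimates
  for (nm in names(est))
    cat(sprintf("  %-6s = %10.4f (se %.4f)\n", nm, est[[nm]], x$se[[nm]]))
  invisible(x)
}
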