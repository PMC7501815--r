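#' Base leaf width at reference radiation
#'
#' The rank profile of leaf width is a Gaussian bell centred at
#' `B_W = beta_w * n_final` with spread `G_W = sigma_w * n_final`, scaled by
#' the genotypic width of leaf 6:
#' `W_base(n) = w6 * exp(-(n - B_W)^2 / (2 G_W^2))`.
#' Unlike the elongation bell, this profile is not renormalised at rank 6,
#' so `base_width(6)` is close to but not exactly `w6` (the discrepancy is
#' below 0.2% for typical parameter values).
#'
#' @param n Leaf rank(s).
#' @param g,k Genotype parameters and species constants.
#' @param allow_real If `TRUE`, allow continuous (non-integer) ranks.
#' @return Base width (mm).
#' @export
base_width <- function(n, g, k = species_constants(), allow_real = FALSE) {
  if (!allow_real) check_rank(n, g$n_final)
  b_w <- k$beta_w * g$n_final
  g_w <- k$sigma_w * g$n_final
  g$w6 * exp(-(n - b_w)^2 / (2 * g_w^2))
}

#' Radiation effect on leaf width
#'
#' Linear effect of mean intercepted radiation during the widening window:
#' `r_rad * (rad_i - rad_base)`. It is zero at `rad_base` (0.15 MJ per plant
#' per day) and may be negative under very low light.
#'
#' @param mean_rad_i Mean daily plant intercepted radiation over the
#'   widening window so far (MJ per plant per day), >= 0.
#' @param r_rad Genotypic widening sensitivity (mm per MJ).
#' @param k A [species_constants()] object.
#' @return Width offset (mm).
#' @export
radiation_effect <- function(mean_rad_i, r_rad, k = species_constants()) {
  if (any(!is.finite(mean_rad_i)) || any(mean_rad_i < 0))
    stop("'mean_rad_i' must be >= 0", call. = FALSE)
  r_rad * (mean_rad_i - k$rad_base)
}

# Daily width trajectory of one leaf. Radiation is averaged over the days
# whose thermal-time midpoints fall inside the widening window, as a running
# mean up to the current day; the width is frozen once the window closes and
# floored (default 1 mm) against extreme low light.
width_series <- function(n, schedule, env, g, k = species_constants(),
                         width_floor = 1) {
  check_rank(n, g$n_final)
  row <- schedule[schedule$rank == n, ]
  nd <- nrow(env)
  width <- numeric(nd)
  if (nd == 0L) return(data.frame(day = integer(), width_mm = numeric()))
  active <- env$tt_mid >= row$tt_beg_w & env$tt_mid <= row$tt_end_w
  if (!any(active)) {
    # window narrower than one day: use the day containing its midpoint
    mid <- (row$tt_beg_w + row$tt_end_w) / 2
    j <- which(env$tt0 <= mid & env$tt1 >= mid)
    if (length(j)) active[j[1L]] <- TRUE
  }
  idx <- which(active)
  if (length(idx)) {
    run_mean <- cumsum(env$rad[idx]) / seq_along(idx)
    w_active <- pmax(width_floor,
                     base_width(n, g, k) +
                       radiation_effect(run_mean, g$r_rad, k))
    width[idx] <- w_active
    first <- idx[1L]; last <- idx[length(idx)]
    if (last < nd) width[(last + 1L):nd] <- w_active[length(w_active)]
    if (first > 1L) width[seq_len(first - 1L)] <- 0
  }
  out <- data.frame(day = env$day, width_mm = width)
  attr(out, "truncated") <- env$tt1[nd] < row$tt_end_w
  out
}

#' Leaf width on a given day
#'
#' Width of the leaf of rank `n` on day `day`: 0 before the widening window
#' opens, `W_base(n)` plus the radiation effect of the running window-mean
#' intercepted radiation while the window is open, and frozen at its final
#' value after the window closes.
#'
#' @param n Leaf rank.
#' @param day Day index (must be present in `env$day`).
#' @param schedule,env,g,k As in [integrate_length()].
#' @param width_floor Minimum width (mm) while widening, guarding against
#'   negative widths under extreme low light.
#' @return Width (mm).
#' @export
width_at <- function(n, day, schedule, env, g, k = species_constants(),
                     width_floor = 1) {
  ws <- width_series(n, schedule, env, g, k, width_floor)
  j <- match(day, ws$day)
  if (any(is.na(j))) stop("'day' not present in the environment series",
                          call. = FALSE)
  ws$width_mm[j]
}
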