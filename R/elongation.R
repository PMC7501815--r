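#' Rank-normalised maximum leaf elongation rate
#'
#' The maximum elongation rate varies with leaf rank as a Gaussian bell
#' centred at rank `B_L = beta_l * n_final` with spread
#' `G_L = sigma_l * n_final`, scaled so that the value at rank 6 (the
#' reference leaf whose rate is the genotypic parameter `a6`) is exactly 1.
#'
#' @param n Leaf rank(s); integers in `1..n_final` (use
#'   `allow_real = TRUE` internally for continuous evaluation).
#' @param n_final Final leaf number.
#' @param k A [species_constants()] object.
#' @param allow_real If `TRUE`, skip the integer-rank check (continuous
#'   evaluation of the bell, e.g. at its peak `B_L`).
#' @return Dimensionless rate multiplier; equals 1 at rank 6.
#' @examples
#' normalized_ler(6, 16)   # exactly 1
#' normalized_ler(12, 16)
#' @export
normalized_ler <- function(n, n_final, k = species_constants(),
                           allow_real = FALSE) {
  if (!allow_real) check_rank(n, n_final)
  b_l <- k$beta_l * n_final
  g_l <- k$sigma_l * n_final
  theta_l <- 1 / exp(-(6 - b_l)^2 / (2 * g_l^2))
  theta_l * exp(-(n - b_l)^2 / (2 * g_l^2))
}

# elongation rate per degree-day under given VPD (kPa) and PSI (MPa);
# negative rates under extreme stress are clamped to zero
ler_per_dd <- function(g, vpd, psi) {
  pmax(0, g$a6 + g$b * vpd + g$c * psi)
}

#' Elongation increment of one leaf on one day
#'
#' The daily length increment of the leaf of rank `n`:
#' `LER_norm(n) * max(0, a6 + b*VPD + c*PSI) * dtt_eff`, where `dtt_eff` is
#' the part of the day's equivalent thermal time that overlaps the leaf's
#' linear-elongation window `[tt_bl, tt_el]` (boundary days contribute
#' pro-rated thermal time).
#'
#' @param n Leaf rank.
#' @param day_record One row of an [environment_series()] (columns `vpd`,
#'   `psi`, `tt0`, `tt1`).
#' @param schedule A [build_schedule()] result.
#' @param g,k Genotype parameters and species constants.
#' @return Length increment (mm) for that day.
#' @export
instantaneous_ler <- function(n, day_record, schedule, g,
                              k = species_constants()) {
  check_rank(n, g$n_final)
  row <- schedule[schedule$rank == n, ]
  dtt_eff <- pmax(0, pmin(row$tt_el, day_record$tt1) -
                     pmax(row$tt_bl, day_record$tt0))
  normalized_ler(n, g$n_final, k) * ler_per_dd(g, day_record$vpd,
                                               day_record$psi) * dtt_eff
}

#' Integrate leaf length over an environment series
#'
#' Day-by-day summation of the elongation increments of one leaf from plant
#' emergence, giving the cumulative length trajectory: zero before
#' `tt_bl(n)`, growing through the linear-elongation window, constant at the
#' final length after `tt_el(n)`.
#'
#' @param n Leaf rank.
#' @param schedule A [build_schedule()] result sharing the thermal-time
#'   origin (plant emergence) with `env`.
#' @param env An [environment_series()].
#' @param g,k Genotype parameters and species constants.
#' @return A data frame with columns `day`, `tt1` (cumulative thermal time
#'   at end of day) and `length_mm`; attribute `truncated` is `TRUE` when
#'   the series ends before the leaf's `tt_el`.
#' @export
integrate_length <- function(n, schedule, env, g, k = species_constants()) {
  check_rank(n, g$n_final)
  row <- schedule[schedule$rank == n, ]
  dtt_eff <- pmax(0, pmin(row$tt_el, env$tt1) - pmax(row$tt_bl, env$tt0))
  inc <- normalized_ler(n, g$n_final, k) *
    ler_per_dd(g, env$vpd, env$psi) * dtt_eff
  out <- data.frame(day = env$day, tt1 = env$tt1, length_mm = cumsum(inc))
  attr(out, "truncated") <- nrow(env) == 0L || env$tt1[nrow(env)] < row$tt_el
  out
}

#' Closed-form final leaf length under constant forcing
#'
#' Analytic value of the integrated length when VPD, PSI and daily thermal
#' time are constant: rate times window duration,
#' `LER_norm(n) * max(0, a6 + b*VPD + c*PSI) * (tt_el(n) - tt_bl(n))`.
#' Serves as the exact oracle for [integrate_length()] under constant
#' forcing.
#'
#' @param n Leaf rank.
#' @param schedule A [build_schedule()] result.
#' @param vpd,psi The constant forcing (kPa, MPa).
#' @param g,k Genotype parameters and species constants.
#' @return Final leaf length (mm).
#' @export
closed_form_length <- function(n, schedule, vpd, psi, g,
                               k = species_constants()) {
  check_rank(n, g$n_final)
  row <- schedule[schedule$rank == n, ]
  normalized_ler(n, g$n_final, k) * ler_per_dd(g, vpd, psi) *
    (row$tt_el - row$tt_bl)
}
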