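check_rank <- function(n, n_final) {
  if (length(n) == 0L || any(!is.finite(n)) || any(n < 1) ||
      any(n > n_final) || any(n != round(n)))
    stop("leaf rank must be an integer between 1 and n_final (", n_final,
         ")", call. = FALSE)
  invisible(n)
}

#' Thermal time of leaf tip appearance
#'
#' Linear in rank: `a_tip * n + b_tip`, the phyllochron regression.
#'
#' @param n Leaf rank(s), integers in `1..n_final` (counted acropetally,
#'   first true leaf = 1).
#' @param g A [genotype_parameters()] object.
#' @return Thermal time since plant emergence (degree-days).
#' @export
tt_tip <- function(n, g) {
  check_rank(n, g$n_final)
  g$a_tip * n + g$b_tip
}

#' Thermal time of the beginning of linear elongation
#'
#' Coincides with tip appearance for ranks up to `n_bl_lim` (= 6); for
#' higher ranks the slope is reduced by the factor `k_bl`, with the
#' intercept constructed so the two segments join continuously at
#' `n_bl_lim`.
#'
#' @inheritParams tt_tip
#' @param k A [species_constants()] object.
#' @return Thermal time since plant emergence (degree-days).
#' @export
tt_begin_linear <- function(n, g, k = species_constants()) {
  check_rank(n, g$n_final)
  b_bl <- g$b_tip + k$n_bl_lim * g$a_tip * (1 - k$k_bl)
  ifelse(n <= k$n_bl_lim,
         g$a_tip * n + g$b_tip,
         k$k_bl * g$a_tip * n + b_bl)
}

#' Thermal time of ligule appearance
#'
#' Two linear segments in rank with a breakpoint at the (real-valued) rank
#' `alpha_ll * n_final`; the post-breakpoint slope is `k_ll * a_ll1` and the
#' intercept is constructed so the segments join continuously at the
#' breakpoint. The rank is compared directly with the real-valued
#' breakpoint; no rounding is applied.
#'
#' @inheritParams tt_begin_linear
#' @return Thermal time since plant emergence (degree-days).
#' @export
tt_ligule <- function(n, g, k = species_constants()) {
  check_rank(n, g$n_final)
  n_star <- k$alpha_ll * g$n_final
  b_ll2 <- g$b_ll1 + g$a_ll1 * n_star * (1 - k$k_ll)
  ifelse(n <= n_star,
         g$a_ll1 * n + g$b_ll1,
         k$k_ll * g$a_ll1 * n + b_ll2)
}

#' Thermal time of the end of linear elongation
#'
#' A leaf ends linear elongation `a_lag * n` degree-days before its ligule
#' appears; the top `n_last` leaves (default 2) end elongation together, at
#' the value of rank `n_final - n_last + 1`.
#'
#' @inheritParams tt_begin_linear
#' @return Thermal time since plant emergence (degree-days).
#' @export
tt_end_linear <- function(n, g, k = species_constants()) {
  check_rank(n, g$n_final)
  n_cap <- g$n_final - k$n_last + 1
  n_eff <- pmin(n, n_cap)
  tt_ligule(n_eff, g, k) - k$a_lag * n_eff
}

#' Thermal-time window of leaf widening
#'
#' Widening starts with linear elongation and ends `lag_w` degree-days
#' (default 39) before linear elongation ends.
#'
#' @inheritParams tt_begin_linear
#' @return A list with numeric vectors `tt_beg_w` and `tt_end_w`
#'   (degree-days since emergence).
#' @export
widening_window <- function(n, g, k = species_constants()) {
  beg <- tt_begin_linear(n, g, k)
  end <- tt_end_linear(n, g, k) - k$lag_w
  bad <- which(end <= beg)
  if (length(bad))
    stop("inconsistent schedule: widening window is empty at rank ",
         n[bad[1L]], call. = FALSE)
  list(tt_beg_w = beg, tt_end_w = end)
}

#' Full per-rank developmental schedule of a plant
#'
#' Evaluates all six developmental events for every rank `1..n_final`: tip
#' appearance, beginning of linear elongation, ligule appearance, end of
#' linear elongation, and the widening window.
#'
#' @inheritParams tt_begin_linear
#' @return A `leaf_schedule` data frame with columns `rank`, `tt_tip`,
#'   `tt_bl`, `tt_ll`, `tt_el`, `tt_beg_w`, `tt_end_w` (degree-days since
#'   plant emergence), one row per rank.
#' @examples
#' g <- genotype_parameters(16, 40, 20, 60, 100, 5, -2.3, 2.5, 70, 10)
#' head(build_schedule(g))
#' @export
build_schedule <- function(g, k = species_constants()) {
  if (!inherits(g, "genotype_parameters"))
    stop("'g' must be a genotype_parameters object", call. = FALSE)
  n <- seq_len(g$n_final)
  w <- widening_window(n, g, k)
  out <- data.frame(rank = n,
                    tt_tip = tt_tip(n, g),
                    tt_bl = tt_begin_linear(n, g, k),
                    tt_ll = tt_ligule(n, g, k),
                    tt_el = tt_end_linear(n, g, k),
                    tt_beg_w = w$tt_beg_w,
                    tt_end_w = w$tt_end_w)
  if (any(out$tt_bl >= out$tt_el))
    stop("inconsistent schedule: elongation window is empty at rank ",
         out$rank[which(out$tt_bl >= out$tt_el)[1L]], call. = FALSE)
  class(out) <- c("leaf_schedule", "data.frame")
  out
}
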