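#' Genotype-specific model parameters
#'
#' Bundles the ten genotype-specific parameters that drive the development of
#' one plant: final leaf number, the two linear stage regressions (tip
#' appearance and ligule appearance against thermal time), the elongation
#' parameters of leaf 6 with its environmental sensitivities, and the
#' widening parameters of leaf 6.
#'
#' The two environmental sensitivities of elongation, `b` and `c`, are stored
#' on the absolute scale at which they enter the elongation rate (mm per
#' degree-day per kPa and per MPa respectively): the instantaneous rate of
#' leaf 6 is `a6 + b * VPD + c * PSI`. Calibration routines that estimate
#' sensitivities on the relative scale (intercept normalised to 1) must be
#' converted with [to_absolute_sensitivities()] before being used here.
#'
#' @param n_final Final (maximum) number of leaves; integer, at least 8 so
#'   that both rank breakpoints of the schedule fall strictly inside the rank
#'   range.
#' @param a_tip Phyllochron: thermal time between successive leaf tip
#'   appearances (degree-days per leaf), > 0.
#' @param b_tip Intercept of the tip-appearance regression (degree-days).
#' @param a_ll1 Thermal time between successive ligule appearances below the
#'   ligulation breakpoint (degree-days per leaf), > 0.
#' @param b_ll1 Intercept of the ligulation regression (degree-days).
#' @param a6 Maximum elongation rate of leaf 6 (mm per degree-day), > 0.
#' @param b Sensitivity of the elongation rate to vapour pressure deficit
#'   (mm per degree-day per kPa); typically negative.
#' @param c Sensitivity of the elongation rate to soil water potential
#'   (mm per degree-day per MPa); typically positive (rate falls as the soil
#'   dries, i.e. as PSI becomes more negative).
#' @param w6 Width of leaf 6 at the reference intercepted radiation of
#'   1.5 MJ per plant per day (mm), > 0.
#' @param r_rad Sensitivity of leaf widening to intercepted radiation
#'   (mm per MJ).
#' @param name Optional genotype label carried through outputs.
#'
#' @return An object of class `genotype_parameters` (a named list).
#' @seealso [species_constants()], [build_schedule()], [simulate_plant()]
#' @examples
#' g <- genotype_parameters(n_final = 16, a_tip = 40, b_tip = 20,
#'                          a_ll1 = 60, b_ll1 = 100, a6 = 5,
#'                          b = -2.3, c = 2.5, w6 = 70, r_rad = 10)
#' g
#' @export
genotype_parameters <- function(n_final, a_tip, b_tip, a_ll1, b_ll1,
                                a6, b, c, w6, r_rad, name = "genotype") {
  vals <- list(n_final = n_final, a_tip = a_tip, b_tip = b_tip,
               a_ll1 = a_ll1, b_ll1 = b_ll1, a6 = a6, b = b, c = c,
               w6 = w6, r_rad = r_rad)
  for (k in names(vals)) {
    v <- vals[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("genotype parameter '", k, "' must be a single finite number",
           call. = FALSE)
  }
  if (n_final < 8 || n_final != round(n_final))
    stop("'n_final' must be an integer >= 8", call. = FALSE)
  if (a_tip <= 0) stop("'a_tip' must be > 0", call. = FALSE)
  if (a_ll1 <= 0) stop("'a_ll1' must be > 0", call. = FALSE)
  if (a6 <= 0) stop("'a6' must be > 0", call. = FALSE)
  if (w6 <= 0) stop("'w6' must be > 0", call. = FALSE)
  out <- c(vals, list(name = as.character(name)[1L]))
  out$n_final <- as.integer(n_final)
  class(out) <- "genotype_parameters"
  out
}

#' @export
print.genotype_parameters <- function(x, ...) {
  cat("<genotype_parameters> ", x$name, "\n", sep = "")
  cat(sprintf("  n_final = %d leaves\n", x$n_final))
  cat(sprintf("  tip:    a_tip = %g, b_tip = %g (degree-days)\n",
              x$a_tip, x$b_tip))
  cat(sprintf("  ligule: a_ll1 = %g, b_ll1 = %g (degree-days)\n",
              x$a_ll1, x$b_ll1))
  cat(sprintf("  elongation: a6 = %g mm/Cd, b = %g mm/Cd/kPa, c = %g mm/Cd/MPa\n",
              x$a6, x$b, x$c))
  cat(sprintf("  widening:   w6 = %g mm, r_rad = %g mm/MJ\n", x$w6, x$r_rad))
  invisible(x)
}

#' Non-genotypic species constants of the development model
#'
#' The twelve constants shared by all maize genotypes in the development
#' model. Defaults are the published values; any of them can be overridden
#' (for sensitivity analyses or other species), which is reported in run
#' metadata.
#'
#' @param k_bl Ratio between the tip-appearance and
#'   beginning-of-linear-elongation slopes for upper leaves (dimensionless).
#' @param n_bl_lim Rank at which the beginning of linear elongation stops
#'   coinciding with tip appearance (leaves).
#' @param k_ll Ratio of the post- to pre-breakpoint ligulation slopes
#'   (dimensionless).
#' @param alpha_ll Position of the ligulation breakpoint as a fraction of
#'   `n_final` (dimensionless, < 1).
#' @param n_last Number of topmost leaves that end linear elongation at the
#'   same thermal time (leaves).
#' @param a_lag Thermal-time lag per rank between the end of linear
#'   elongation and ligule appearance (degree-days per leaf).
#' @param lag_w Thermal-time lag between the ends of widening and of linear
#'   elongation (degree-days).
#' @param beta_l Rank of the fastest-elongating leaf as a fraction of
#'   `n_final` (dimensionless).
#' @param sigma_l Spread of the elongation-rate bell as a fraction of
#'   `n_final` (dimensionless).
#' @param beta_w Rank of the widest leaf as a fraction of `n_final`
#'   (dimensionless).
#' @param sigma_w Spread of the base-width bell as a fraction of `n_final`
#'   (dimensionless).
#' @param rad_base Intercepted radiation at which the radiation effect on
#'   width is zero (MJ per plant per day).
#'
#' @return An object of class `species_constants` (a named list).
#' @examples
#' species_constants()
#' species_constants(k_bl = 0.75) # override one constant
#' @export
species_constants <- function(k_bl = 0.708, n_bl_lim = 6, k_ll = 0.454,
                              alpha_ll = 0.52, n_last = 2, a_lag = 5.4,
                              lag_w = 39, beta_l = 0.68, sigma_l = 0.46,
                              beta_w = 0.41, sigma_w = 0.69,
                              rad_base = 0.15) {
  k <- list(k_bl = k_bl, n_bl_lim = n_bl_lim, k_ll = k_ll,
            alpha_ll = alpha_ll, n_last = n_last, a_lag = a_lag,
            lag_w = lag_w, beta_l = beta_l, sigma_l = sigma_l,
            beta_w = beta_w, sigma_w = sigma_w, rad_base = rad_base)
  for (nm in names(k)) {
    v <- k[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("species constant '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  if (alpha_ll >= 1)
    stop("'alpha_ll' must be < 1 (breakpoint inside the rank range)",
         call. = FALSE)
  class(k) <- "species_constants"
  k
}

#' @export
print.species_constants <- function(x, ...) {
  cat("<species_constants>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-9s = %g\n", nm, x[[nm]]))
  invisible(x)
}

as_species_constants <- function(k) {
  if (inherits(k, "species_constants")) return(k)
  do.call(species_constants, as.list(k))
}
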