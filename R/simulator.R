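#' Simulate the development of every leaf of one plant
#'
#' Builds the developmental schedule for the genotype, then integrates leaf
#' elongation and widening for every rank over the supplied environment
#' series. Leaves develop independently; their only coupling is the shared
#' schedule. The time step is the day; all rates are per degree-day and are
#' converted through the day's equivalent thermal time.
#'
#' @param g A [genotype_parameters()] object.
#' @param env An [environment_series()] starting at plant emergence (day 0
#'   of the series is thermal time 0).
#' @param k A [species_constants()] object.
#' @param width_floor Minimum leaf width (mm) during widening.
#' @return A `plant_simulation` list with elements
#'   \describe{
#'     \item{schedule}{the [build_schedule()] data frame}
#'     \item{daily}{long data frame `rank, day, tt1, length_mm, width_mm`}
#'     \item{final_profile}{data frame `rank, length_mm, width_mm` of final
#'       dimensions}
#'     \item{flags}{character vector of warnings (e.g. truncation of the
#'       series before the last leaf finished)}
#'     \item{genotype, constants}{the inputs, for provenance}
#'   }
#' @examples
#' g <- genotype_parameters(16, 40, 20, 60, 100, 5, -2.3, 2.5, 70, 10)
#' env <- environment_series(0:59, temperature = 28, vpd = 1,
#'                           psi = -0.05, rad = 1.15)
#' sim <- simulate_plant(g, env)
#' sim$final_profile
#' @export
simulate_plant <- function(g, env, k = species_constants(),
                           width_floor = 1) {
  if (!inherits(env, "environment_series"))
    stop("'env' must be an environment_series", call. = FALSE)
  if (nrow(env) == 0L)
    stop("'env' must cover at least one day", call. = FALSE)
  sched <- tryCatch(build_schedule(g, k),
                    error = function(e) stop("genotype '", g$name, "': ",
                                             conditionMessage(e),
                                             call. = FALSE))
  flags <- character()
  daily <- vector("list", g$n_final)
  for (n in seq_len(g$n_final)) {
    len <- integrate_length(n, sched, env, g, k)
    wid <- width_series(n, sched, env, g, k, width_floor)
    if (isTRUE(attr(len, "truncated")) || isTRUE(attr(wid, "truncated")))
      flags <- c(flags, sprintf(
        "rank %d: environment series ends before development completes", n))
    daily[[n]] <- data.frame(rank = n, day = env$day, tt1 = env$tt1,
                             length_mm = len$length_mm,
                             width_mm = wid$width_mm)
  }
  daily <- do.call(rbind, daily)
  last <- daily[daily$day == env$day[nrow(env)], ]
  final_profile <- data.frame(rank = last$rank, length_mm = last$length_mm,
                              width_mm = last$width_mm)
  structure(list(schedule = sched, daily = daily,
                 final_profile = final_profile, flags = flags,
                 genotype = g, constants = k,
                 width_floor = width_floor),
            class = "plant_simulation")
}

#' @export
print.plant_simulation <- function(x, ...) {
  cat("<plant_simulation> ", x$genotype$name, ": ", x$genotype$n_final,
      " leaves over ", length(unique(x$daily$day)), " days\n", sep = "")
  s <- profile_summary(x)
  cat(sprintf("  longest leaf: rank %d, %.1f mm\n",
              s$longest_rank, s$longest_length_mm))
  cat(sprintf("  widest leaf:  rank %d, %.1f mm\n",
              s$widest_rank, s$widest_width_mm))
  if (length(x$flags)) cat("  flags:", length(x$flags), "\n")
  invisible(x)
}

#' Summary statistics of a simulated leaf profile
#'
#' @param result A [simulate_plant()] result.
#' @return A list: rank and length of the longest leaf, rank and width of
#'   the widest leaf, cumulative plant leaf length (mm), and whether the
#'   widest leaf sits above the longest one.
#' @export
profile_summary <- function(result) {
  fp <- result$final_profile
  il <- which.max(fp$length_mm)
  iw <- which.max(fp$width_mm)
  list(longest_rank = fp$rank[il], longest_length_mm = fp$length_mm[il],
       widest_rank = fp$rank[iw], widest_width_mm = fp$width_mm[iw],
       cumulative_length_mm = sum(fp$length_mm),
       widest_above_longest = fp$rank[iw] > fp$rank[il])
}

#' Leaf area from final length and width
#'
#' Area of each leaf as `shape_factor * length * width`, the usual
#' rectangular-envelope correction for the lanceolate maize blade.
#'
#' @param result A [simulate_plant()] result.
#' @param shape_factor Fraction of the length-by-width rectangle occupied by
#'   the blade, in `(0, 1]`; default 0.75.
#' @return A data frame `rank, area_cm2`, with the per-plant total in
#'   attribute `plant_area_cm2` and the factor in attribute `shape_factor`.
#' @export
leaf_area <- function(result, shape_factor = 0.75) {
  if (!is.numeric(shape_factor) || length(shape_factor) != 1L ||
      shape_factor <= 0 || shape_factor > 1)
    stop("'shape_factor' must be in (0, 1]", call. = FALSE)
  fp <- result$final_profile
  area <- shape_factor * fp$length_mm * fp$width_mm / 100 # mm^2 -> cm^2
  out <- data.frame(rank = fp$rank, area_cm2 = area)
  attr(out, "plant_area_cm2") <- sum(area)
  attr(out, "shape_factor") <- shape_factor
  out
}
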