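# Synthetic environment scenarios and noisy observation sets with the
# statistical structure the calibration procedures assume, so the whole
# chain (schedule -> simulation -> observation -> calibration) can be
# exercised without field data.

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic environment scenario
#'
#' Three scenario kinds are supported. `constant`: fixed temperature, VPD,
#' soil water potential and radiation every day. `seasonal`: a sinusoidal
#' temperature and VPD season around the supplied means. `drydown`: the
#' platform drought protocol — soil water potential held at a well-watered
#' plateau, then dried over a few days to a first target (default -0.4 MPa),
#' held, then dried again to a second target (default -0.6 MPa) and held to
#' the end.
#'
#' @param kind `"constant"`, `"seasonal"` or `"drydown"`.
#' @param duration Number of days (>= 1), starting at day 0 (emergence).
#' @param temperature Daily mean temperature (deg C).
#' @param temp_amplitude Seasonal half-amplitude of temperature (deg C;
#'   `seasonal` only).
#' @param vpd Daily mean VPD (kPa).
#' @param vpd_amplitude Seasonal half-amplitude of VPD (kPa; `seasonal`
#'   only).
#' @param psi Well-watered soil water potential (MPa, <= 0).
#' @param psi_targets Successive drydown targets (MPa; `drydown` only).
#' @param drydown_start Day the first drying begins (`drydown` only).
#' @param drydown_days Days each drying ramp takes.
#' @param plateau_days Days each target is held before the next ramp.
#' @param rad Daily plant intercepted radiation (MJ per plant per day).
#' @param noise_sd Gaussian day-to-day jitter added to temperature and VPD
#'   (same units); 0 for a fully deterministic series.
#' @param seed Seed used when `noise_sd > 0`.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(kind = c("constant", "seasonal", "drydown"),
                          duration = 120, temperature = 28,
                          temp_amplitude = 4, vpd = 1, vpd_amplitude = 0.5,
                          psi = -0.05, psi_targets = c(-0.4, -0.6),
                          drydown_start = 30, drydown_days = 6,
                          plateau_days = 8, rad = 1, noise_sd = 0,
                          seed = 1) {
  kind <- match.arg(kind)
  if (duration < 1) stop("'duration' must be >= 1 day", call. = FALSE)
  if (psi > 0 || any(psi_targets > 0))
    stop("soil water potentials must be <= 0", call. = FALSE)
  structure(list(kind = kind, duration = as.integer(duration),
                 temperature = temperature, temp_amplitude = temp_amplitude,
                 vpd = vpd, vpd_amplitude = vpd_amplitude, psi = psi,
                 psi_targets = psi_targets,
                 drydown_start = as.integer(drydown_start),
                 drydown_days = as.integer(drydown_days),
                 plateau_days = as.integer(plateau_days), rad = rad,
                 noise_sd = noise_sd, seed = seed),
            class = "scenario_spec")
}

#' Generate an environment series from a scenario specification
#'
#' @param spec A [scenario_spec()].
#' @param config A [thermal_config()].
#' @return An [environment_series()]; deterministic for a fixed spec (and
#'   seed, when `noise_sd > 0`).
#' @examples
#' env <- generate_environment(scenario_spec("drydown", duration = 90))
#' range(env$psi)
#' @export
generate_environment <- function(spec, config = thermal_config()) {
  if (!inherits(spec, "scenario_spec"))
    stop("'spec' must be a scenario_spec", call. = FALSE)
  d <- seq_len(spec$duration) - 1L
  temp <- rep(spec$temperature, spec$duration)
  vpd <- rep(spec$vpd, spec$duration)
  psi <- rep(spec$psi, spec$duration)
  if (spec$kind == "seasonal") {
    phase <- 2 * pi * d / max(spec$duration, 2L)
    temp <- temp + spec$temp_amplitude * sin(phase)
    vpd <- pmax(0, vpd + spec$vpd_amplitude * sin(phase))
  }
  if (spec$kind == "drydown") {
    t0 <- spec$drydown_start
    from <- spec$psi
    for (target in spec$psi_targets) {
      ramp_end <- t0 + spec$drydown_days
      in_ramp <- d >= t0 & d < ramp_end
      psi[in_ramp] <- from + (target - from) * (d[in_ramp] - t0 + 1) /
        spec$drydown_days
      psi[d >= ramp_end] <- target
      from <- target
      t0 <- ramp_end + spec$plateau_days
    }
  }
  if (spec$noise_sd > 0) {
    jit <- with_seed(spec$seed,
                     matrix(stats::rnorm(2L * spec$duration,
                                         sd = spec$noise_sd), ncol = 2L))
    temp <- temp + jit[, 1L]
    vpd <- pmax(0, vpd + jit[, 2L])
  }
  environment_series(d, temp, vpd, psi, rep(spec$rad, spec$duration),
                     config)
}

#' Generate noisy longitudinal observations from a simulated plant
#'
#' Emulates a field/platform observation protocol on a finished simulation:
#' a set of reference plants is scored every `every_days` days for the
#' number of appeared tips and ligulated leaves (each plant's event times
#' jittered by Gaussian timing noise), and on each scoring date a batch of
#' plants is dissected, yielding leaf lengths and widths per rank with
#' multiplicative Gaussian noise.
#'
#' The noise defaults (timing sd 10 degree-days, dimension CV 5%) are
#' synthetic test fixtures, not estimates from any measured error model.
#'
#' @param result A [simulate_plant()] result.
#' @param every_days Scoring cadence in days (default 2).
#' @param n_plants Number of scored reference plants (default 15).
#' @param diss_plants Number of plants dissected per scoring date
#'   (default 10).
#' @param timing_sd Gaussian sd of per-plant, per-rank event-time jitter
#'   (degree-days); 0 for noise-free counts.
#' @param dim_cv Coefficient of variation of dissected lengths and widths
#'   per plant; 0 for noise-free dissections.
#' @param seed Seed; the output is deterministic per seed.
#' @return A list of data frames: `stage_counts` (`plant, day, tt, n_tip,
#'   n_ligule`) and `dissections` (`plant, day, tt, rank, length_mm,
#'   width_mm`).
#' @export
generate_observations <- function(result, every_days = 2, n_plants = 15,
                                  diss_plants = 10, timing_sd = 10,
                                  dim_cv = 0.05, seed = 1) {
  if (!inherits(result, "plant_simulation"))
    stop("'result' must be a plant_simulation", call. = FALSE)
  sched <- result$schedule
  daily <- result$daily
  days <- sort(unique(daily$day))
  obs_days <- days[seq(1L, length(days)) %% every_days == 0L]
  tt_of_day <- daily$tt1[match(obs_days, daily$day)]
  nf <- result$genotype$n_final
  with_seed(seed, {
    counts <- do.call(rbind, lapply(seq_len(n_plants), function(p) {
      tip_p <- sched$tt_tip + stats::rnorm(nf, sd = timing_sd)
      lig_p <- sched$tt_ll + stats::rnorm(nf, sd = timing_sd)
      data.frame(plant = p, day = obs_days, tt = tt_of_day,
                 n_tip = vapply(tt_of_day,
                                function(x) sum(tip_p <= x), integer(1)),
                 n_ligule = vapply(tt_of_day,
                                   function(x) sum(lig_p <= x), integer(1)))
    }))
    # counts may dip with timing noise; enforce monotone scoring per plant
    counts <- do.call(rbind, lapply(split(counts, counts$plant),
                                    function(d) {
      d$n_tip <- cummax(d$n_tip); d$n_ligule <- cummax(d$n_ligule); d
    }))
    rownames(counts) <- NULL
    base <- daily[daily$day %in% obs_days, c("day", "tt1", "rank",
                                             "length_mm", "width_mm")]
    names(base)[2L] <- "tt"
    dis <- do.call(rbind, lapply(seq_len(diss_plants), function(p) {
      d <- base
      m <- nrow(d)
      d$length_mm <- d$length_mm * (1 + stats::rnorm(m, sd = dim_cv))
      d$width_mm <- d$width_mm * (1 + stats::rnorm(m, sd = dim_cv))
      cbind(plant = p, d)
    }))
    rownames(dis) <- NULL
    list(stage_counts = counts, dissections = dis)
  })
}
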