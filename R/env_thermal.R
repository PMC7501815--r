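#' Thermal-time response settings
#'
#' Cardinal temperatures of the piecewise-linear thermal-time response used
#' to convert temperature into developmental (equivalent) thermal time. The
#' response is 0 at or below `t_base`, rises linearly to `t_opt_lo - t_base`
#' degree-days per day at `t_opt_lo`, stays flat up to `t_opt_hi`, and falls
#' linearly back to 0 at `t_max`. Defaults are maize cardinal temperatures.
#'
#' @param t_base Base temperature below which no thermal time accrues (deg C).
#' @param t_opt_lo Lower bound of the optimal plateau (deg C).
#' @param t_opt_hi Upper bound of the optimal plateau (deg C).
#' @param t_max Temperature above which no thermal time accrues (deg C).
#' @return A `thermal_config` object.
#' @examples
#' thermal_config()
#' @export
thermal_config <- function(t_base = 8, t_opt_lo = 30, t_opt_hi = 34,
                           t_max = 44) {
  if (!(t_base < t_opt_lo && t_opt_lo <= t_opt_hi && t_opt_hi < t_max))
    stop("cardinal temperatures must satisfy t_base < t_opt_lo <= t_opt_hi < t_max",
         call. = FALSE)
  structure(list(t_base = t_base, t_opt_lo = t_opt_lo,
                 t_opt_hi = t_opt_hi, t_max = t_max),
            class = "thermal_config")
}

#' @export
print.thermal_config <- function(x, ...) {
  cat(sprintf("<thermal_config> base %g, optimum %g-%g, max %g degC\n",
              x$t_base, x$t_opt_lo, x$t_opt_hi, x$t_max))
  invisible(x)
}

# piecewise-linear response, vectorised over temperature
thermal_response <- function(temp, config = thermal_config()) {
  peak <- config$t_opt_lo - config$t_base
  r <- ifelse(temp <= config$t_base, 0,
       ifelse(temp <= config$t_opt_lo, temp - config$t_base,
       ifelse(temp <= config$t_opt_hi, peak,
       ifelse(temp < config$t_max,
              peak * (config$t_max - temp) / (config$t_max - config$t_opt_hi),
              0))))
  pmax(r, 0)
}

#' Equivalent thermal time of one day
#'
#' Converts the temperatures recorded within one day (sub-daily samples, or a
#' single daily mean) into the day's equivalent thermal time, as the mean of
#' the piecewise-linear thermal response over the samples. With all samples
#' in the linear regime this equals the mean temperature excess over
#' `t_base`; it is never negative.
#'
#' @param temperatures Numeric vector of temperatures within one day (deg C).
#' @param config A [thermal_config()].
#' @return Equivalent thermal time of the day (degree-days), >= 0.
#' @examples
#' daily_thermal_time(28)                    # daily mean, linear regime: 20
#' daily_thermal_time(c(15, 22, 30, 25))     # sub-daily samples
#' @export
daily_thermal_time <- function(temperatures, config = thermal_config()) {
  if (length(temperatures) == 0L || !is.numeric(temperatures) ||
      anyNA(temperatures))
    stop("'temperatures' must be a non-empty numeric vector without NA",
         call. = FALSE)
  mean(thermal_response(temperatures, config))
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' Saturation vapour pressure is computed with the Magnus formula
#' `e_s = 0.6108 * exp(17.27 T / (T + 237.3))` kPa (the FAO-56 constants);
#' the deficit is `e_s * (1 - RH)`.
#'
#' @param temperature Air temperature (deg C), between -20 and 60.
#' @param relative_humidity Relative humidity as a fraction in `[0, 1]`.
#' @return Vapour pressure deficit (kPa), >= 0.
#' @examples
#' compute_vpd(25, 0.5) # ~ 1.58 kPa
#' @export
compute_vpd <- function(temperature, relative_humidity) {
  if (any(!is.finite(relative_humidity)) ||
      any(relative_humidity < 0) || any(relative_humidity > 1))
    stop("'relative_humidity' must be a fraction between 0 and 1",
         call. = FALSE)
  if (any(!is.finite(temperature)) ||
      any(temperature < -20) || any(temperature > 60))
    stop("'temperature' must be between -20 and 60 degC", call. = FALSE)
  e_sat <- 0.6108 * exp(17.27 * temperature / (temperature + 237.3))
  e_sat * (1 - relative_humidity)
}

#' Daily environmental forcing with cumulative thermal time
#'
#' Builds the daily forcing series that drives a simulation: one record per
#' day with temperature-derived equivalent thermal time `dtt`, cumulative
#' thermal time `tt0`/`tt1` (start and end of the day; `tt0[1] = 0` at plant
#' emergence) and the day's mean VPD, soil water potential and plant
#' intercepted radiation.
#'
#' @param day Integer day indices (0-based or 1-based), strictly increasing.
#' @param temperature Daily mean temperature (deg C), or a list of numeric
#'   vectors of sub-daily temperatures (one vector per day).
#' @param vpd Daily mean vapour pressure deficit (kPa), >= 0.
#' @param psi Daily mean soil water potential (MPa), <= 0.
#' @param rad Daily plant intercepted radiation (MJ per plant per day), >= 0.
#' @param config A [thermal_config()].
#' @return An `environment_series`: a data frame with columns `day`,
#'   `temperature` (daily mean), `vpd`, `psi`, `rad`, `dtt`, `tt0`, `tt1`
#'   and the thermal-time midpoint `tt_mid`, plus the config stored as an
#'   attribute.
#' @examples
#' env <- environment_series(day = 0:9, temperature = 28, vpd = 1,
#'                           psi = -0.05, rad = 1)
#' head(env)
#' @export
environment_series <- function(day, temperature, vpd, psi, rad,
                               config = thermal_config()) {
  n <- length(day)
  if (n == 0L) {
    out <- data.frame(day = integer(), temperature = numeric(),
                      vpd = numeric(), psi = numeric(), rad = numeric(),
                      dtt = numeric(), tt0 = numeric(), tt1 = numeric(),
                      tt_mid = numeric())
    attr(out, "thermal_config") <- config
    class(out) <- c("environment_series", "data.frame")
    return(out)
  }
  if (any(diff(day) <= 0))
    stop("'day' must be strictly increasing", call. = FALSE)
  if (is.list(temperature)) {
    if (length(temperature) != n)
      stop("one temperature vector per day is required", call. = FALSE)
    dtt <- vapply(temperature, daily_thermal_time, numeric(1),
                  config = config)
    temp_mean <- vapply(temperature, mean, numeric(1))
  } else {
    temp_mean <- rep_len(temperature, n)
    dtt <- thermal_response(temp_mean, config)
  }
  vpd <- rep_len(vpd, n); psi <- rep_len(psi, n); rad <- rep_len(rad, n)
  if (any(vpd < 0)) stop("'vpd' must be >= 0", call. = FALSE)
  if (any(psi > 0)) stop("'psi' (soil water potential) must be <= 0",
                         call. = FALSE)
  if (any(rad < 0)) stop("'rad' must be >= 0", call. = FALSE)
  if (any(dtt < 0)) stop("equivalent thermal time must be >= 0",
                         call. = FALSE)
  tt1 <- cumsum(dtt)
  tt0 <- c(0, tt1[-n])
  out <- data.frame(day = as.integer(day), temperature = temp_mean,
                    vpd = vpd, psi = psi, rad = rad, dtt = dtt,
                    tt0 = tt0, tt1 = tt1, tt_mid = (tt0 + tt1) / 2)
  attr(out, "thermal_config") <- config
  class(out) <- c("environment_series", "data.frame")
  out
}

#' Read a daily or hourly weather table
#'
#' Reads a UTF-8, comma-separated weather file with a header. Required
#' columns: `day` (integer) and either `vpd_kpa` or `rh` (relative humidity,
#' fraction; converted with [compute_vpd()]), plus `temp_c`, `psi_mpa`,
#' `rad_mj`. If an `hour` column is present the rows are sub-daily: thermal
#' time is computed from the hourly temperatures, VPD/PSI are averaged
#' (whole-day mean by default) and radiation is summed per day.
#'
#' @param path Path to the CSV file.
#' @param config A [thermal_config()].
#' @param daylight_vpd If `TRUE` and the file is hourly, the daily VPD is the
#'   mean over hours 6-18 only; the default is the whole-day mean.
#' @return An [environment_series()].
#' @export
read_weather <- function(path, config = thermal_config(),
                         daylight_vpd = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("day", "temp_c", "psi_mpa", "rad_mj")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("weather file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!("vpd_kpa" %in% names(tab)) && !("rh" %in% names(tab)))
    stop("weather file must provide either 'vpd_kpa' or 'rh'", call. = FALSE)
  if (!("vpd_kpa" %in% names(tab)))
    tab$vpd_kpa <- compute_vpd(tab$temp_c, tab$rh)
  if ("hour" %in% names(tab)) {
    sp <- split(tab, tab$day)
    day <- as.integer(names(sp))
    o <- order(day)
    sp <- sp[o]; day <- day[o]
    temps <- lapply(sp, function(d) d$temp_c[order(d$hour)])
    vpd <- vapply(sp, function(d) {
      if (daylight_vpd) {
        dl <- d$hour >= 6 & d$hour <= 18
        if (any(dl)) mean(d$vpd_kpa[dl]) else mean(d$vpd_kpa)
      } else mean(d$vpd_kpa)
    }, numeric(1))
    psi <- vapply(sp, function(d) mean(d$psi_mpa), numeric(1))
    rad <- vapply(sp, function(d) sum(d$rad_mj), numeric(1))
    environment_series(day, temps, vpd, psi, rad, config)
  } else {
    tab <- tab[order(tab$day), ]
    environment_series(tab$day, tab$temp_c, tab$vpd_kpa, tab$psi_mpa,
                       tab$rad_mj, config)
  }
}
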