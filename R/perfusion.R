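# cache for the water-density polynomial (fit once per session)
.relkin_env <- new.env(parent = emptyenv())

water_density_table <- function() {
  path <- system.file("extdata", "water_density_0_80C.csv",
                      package = "relkin", mustWork = TRUE)
  utils::read.csv(path)
}

water_density_poly <- function() {
  if (is.null(.relkin_env$density_coef)) {
    tab <- water_density_table()
    fit <- stats::lm(density_g_ml ~ stats::poly(temperature_c, 4,
                                                raw = TRUE), data = tab)
    .relkin_env$density_coef <- unname(stats::coef(fit))
  }
  .relkin_env$density_coef
}

#' Density of water at atmospheric pressure
#'
#' Degree-4 polynomial fitted to a bundled 17-point reference table of
#' liquid-water densities from 0 to 80 degrees C (5-degree spacing,
#' standard atmosphere). The polynomial reproduces the table to better
#' than 1e-4 g/mL across the range.
#'
#' @param temperature_c Temperature in degrees Celsius, within \[0, 80\]
#'   (vectorised).
#' @return Density in g/mL.
#' @examples
#' water_density(25)  # ~0.99705
#' @export
water_density <- function(temperature_c) {
  if (any(temperature_c < 0 | temperature_c > 80)) {
    stop("`temperature_c` must lie in [0, 80]", call. = FALSE)
  }
  cf <- water_density_poly()
  drop(cbind(1, temperature_c, temperature_c^2, temperature_c^3,
             temperature_c^4) %*% cf)
}

#' Flow rate from a timed mass collection
#'
#' A positive-displacement pump is calibrated by collecting water for a
#' known duration: flow (mL/min) = collected mass (g) / density (g/mL) /
#' duration (min), with the density taken at the collection temperature.
#'
#' @param mass_g Collected water mass in grams.
#' @param temperature_c Water temperature in degrees Celsius.
#' @param minutes Collection duration in minutes, > 0.
#' @return Flow rate in mL/min (vectorised).
#' @examples
#' flow_from_collection(0.12, 25, 60)
#' @export
flow_from_collection <- function(mass_g, temperature_c, minutes) {
  if (any(minutes <= 0)) {
    stop("`minutes` must be positive", call. = FALSE)
  }
  if (any(mass_g < 0)) stop("`mass_g` must be non-negative", call. = FALSE)
  mass_g / (water_density(temperature_c) * minutes)
}

#' Fit the linear pump calibration
#'
#' Converts each calibration record to a flow rate with
#' [flow_from_collection()], averages replicates at each pump speed, and
#' regresses the mean flow on RPM by ordinary least squares.
#'
#' @param records A data.frame with columns `rpm`, `mass_g`,
#'   `temperature_c`, `minutes`; at least two distinct RPM values.
#' @return An object of class `pump_calibration`: list with `slope`
#'   (mL/min per RPM), `intercept` (mL/min), `r_squared`, and the per-RPM
#'   mean flows in `means`.
#' @export
fit_pump_calibration <- function(records) {
  needed <- c("rpm", "mass_g", "temperature_c", "minutes")
  if (!all(needed %in% names(records))) {
    stop("`records` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(records$rpm)) < 2L) {
    stop("need at least two distinct RPM values to fit a calibration line",
         call. = FALSE)
  }
  flow <- flow_from_collection(records$mass_g, records$temperature_c,
                               records$minutes)
  means <- tapply(flow, records$rpm, mean)
  rpm <- as.numeric(names(means))
  flow_mean <- as.numeric(means)
  fit <- stats::lm(flow_mean ~ rpm)
  ss_tot <- sum((flow_mean - mean(flow_mean))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 means = data.frame(rpm = rpm, flow_ml_min = flow_mean)),
            class = "pump_calibration")
}

#' Fraction-collector series from a perfusion run
#'
#' @param flow_rate Perfusion flow rate in uL/min.
#' @param fraction_masses Released mass per collection bin (micrograms),
#'   non-negative.
#' @param m_initial Initially loaded mass (micrograms).
#' @param interval_h Collection bin width in hours (default 2).
#' @param dead_volume_ul Tubing dead volume between chamber and collector
#'   (uL); delays first detection.
#' @return An object of class `fraction_series`.
#' @export
fraction_series <- function(flow_rate, fraction_masses, m_initial,
                            interval_h = 2, dead_volume_ul = 300) {
  if (flow_rate <= 0) stop("`flow_rate` must be positive", call. = FALSE)
  if (interval_h <= 0) stop("`interval_h` must be positive", call. = FALSE)
  if (any(fraction_masses < 0)) {
    stop("`fraction_masses` must be non-negative", call. = FALSE)
  }
  if (m_initial <= 0) stop("`m_initial` must be positive", call. = FALSE)
  if (dead_volume_ul < 0) {
    stop("`dead_volume_ul` must be non-negative", call. = FALSE)
  }
  structure(list(flow_rate = flow_rate,
                 fraction_masses = as.numeric(fraction_masses),
                 m_initial = m_initial, interval_h = interval_h,
                 dead_volume_ul = dead_volume_ul),
            class = "fraction_series")
}

#' Cumulative release curve from fraction-collector bins
#'
#' Running sum of the per-bin masses as a percentage of the initial
#' loading; each value is stamped at the right edge of its collection bin
#' (the mass accumulated over the preceding interval).
#'
#' @param series A [fraction_series()].
#' @param tolerance_pct Warning threshold for cumulative totals above
#'   100%.
#' @return A [release_curve()].
#' @export
cumulative_release_from_fractions <- function(series, tolerance_pct = 5) {
  stopifnot(inherits(series, "fraction_series"))
  cum <- cumsum(series$fraction_masses)
  pct <- 100 * cum / series$m_initial
  if (any(pct > 100 + tolerance_pct)) {
    warning(sprintf(
      "cumulative release reaches %.1f%%, more than %g points above 100%%",
      max(pct), tolerance_pct), call. = FALSE)
  }
  times <- series$interval_h * seq_along(cum)
  release_curve(times, cum, series$m_initial)
}

#' First-detection time implied by the tubing dead volume
#'
#' Fluid released at t = 0 must displace the dead volume before reaching
#' the collector: the raw delay is `dead_volume / flow`, converted to
#' hours and rounded up to the next collection-bin edge. With zero dead
#' volume the first possible detection is the first bin edge
#' (`interval_h`).
#'
#' @param flow_ul_min Flow rate in uL/min, > 0.
#' @param dead_volume_ul Dead volume in uL.
#' @param interval_h Collection bin width in hours.
#' @return First-detection time in hours.
#' @examples
#' dead_time(0.5, 300)  # 10 h at 0.5 uL/min with a 300 uL dead volume
#' @export
dead_time <- function(flow_ul_min, dead_volume_ul, interval_h = 2) {
  if (any(flow_ul_min <= 0)) {
    stop("`flow_ul_min` must be positive", call. = FALSE)
  }
  raw_h <- dead_volume_ul / flow_ul_min / 60
  interval_h * pmax(1, ceiling(raw_h / interval_h - 1e-12))
}

#' End-of-run compartment distribution
#'
#' Mass fractions (as percent of the initial loading) across the gel
#' sections recovered at the end of a perfusion run: the alginate:Matrigel
#' section in the flow direction, the central alginate gel, the
#' nanoparticles within it, and the alginate:Matrigel section against the
#' flow.
#'
#' @param algM_downflow_pct,alginate_core_pct,np_pct,algM_upflow_pct
#'   Compartment percentages, each >= 0.
#' @return An object of class `compartment_distribution` (a named numeric
#'   vector).
#' @export
compartment_distribution <- function(algM_downflow_pct, alginate_core_pct,
                                     np_pct, algM_upflow_pct) {
  v <- c(algM_downflow_pct = algM_downflow_pct,
         alginate_core_pct = alginate_core_pct,
         np_pct = np_pct,
         algM_upflow_pct = algM_upflow_pct)
  if (any(v < 0)) {
    stop("compartment percentages must be non-negative", call. = FALSE)
  }
  structure(v, class = "compartment_distribution")
}

#' Mass-balance closure of a perfusion run
#'
#' Sums the released percentage and all compartment percentages; a full
#' accounting of the initial loading closes at ~100%. Measured data
#' outside the tolerance are flagged with a warning (recovery losses,
#' quantification error), never an error; synthetic pipelines close
#' exactly.
#'
#' @param released_pct Cumulative released percentage at end of run.
#' @param compartment_percents A [compartment_distribution()] or numeric
#'   vector of compartment percentages.
#' @param tolerance_pct Allowed deviation from 100 before flagging
#'   (default 5 percentage points).
#' @return The closure percentage (released + compartments).
#' @export
mass_balance <- function(released_pct, compartment_percents,
                         tolerance_pct = 5) {
  if (released_pct < 0 || any(compartment_percents < 0)) {
    stop("percentages must be non-negative", call. = FALSE)
  }
  closure <- released_pct + sum(compartment_percents)
  if (abs(closure - 100) > tolerance_pct) {
    warning(sprintf(
      "mass balance closes at %.2f%%, outside 100 +/- %g points; ",
      closure, tolerance_pct),
      "record flagged", call. = FALSE)
  }
  closure
}

#' @export
print.pump_calibration <- function(x, ...) {
  cat(sprintf(
    "<pump_calibration> flow = %.4g * RPM + %.4g mL/min (R^2 = %.4f)\n",
    x$slope, x$intercept, x$r_squared))
  invisible(x)
}
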