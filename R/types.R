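#' Cylindrical hydrogel geometry
#'
#' The depot is a cylinder released only through its top face: transport is
#' one-dimensional along the axis, so the radius enters the model solely
#' through the cross-sectional area \eqn{\pi R^2} used to convert the
#' concentration integral into mass.
#'
#' @param radius Cylinder radius in metres.
#' @param height Axial extent \eqn{L} in metres (base at 0, release surface
#'   at \eqn{L}).
#' @return An object of class `hydrogel_geometry`.
#' @examples
#' hydrogel_geometry(radius = 3.25e-3, height = 5e-3)
#' @export
hydrogel_geometry <- function(radius = 3.25e-3, height = 5e-3) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("`radius` must be a single positive number (metres)", call. = FALSE)
  }
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) ||
      height <= 0) {
    stop("`height` must be a single positive number (metres)", call. = FALSE)
  }
  structure(list(radius = radius, height = height),
            class = "hydrogel_geometry")
}

#' Transport parameters of the release model
#'
#' @param d_eff Effective diffusion coefficient of the solute in the gel
#'   (m^2/s), assumed constant in space and time.
#' @param k Overall surface mass-transfer coefficient of the Robin release
#'   condition (m/s). `k = 0` seals the gel.
#' @param c_eq Pseudo-equilibrium concentration at which net release stops
#'   (same units as the concentration field). Electrostatic solute-polymer
#'   interactions make it positive, which caps the release plateau below
#'   100%.
#' @return An object of class `transport_params`.
#' @examples
#' transport_params(d_eff = 1.04e-9, k = 4.13e-5, c_eq = 0)
#' @export
transport_params <- function(d_eff, k, c_eq = 0) {
  if (!is.numeric(d_eff) || length(d_eff) != 1L || !is.finite(d_eff) ||
      d_eff <= 0) {
    stop("`d_eff` must be a single positive number (m^2/s)", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    stop("`k` must be a single non-negative number (m/s)", call. = FALSE)
  }
  if (!is.numeric(c_eq) || length(c_eq) != 1L || !is.finite(c_eq) ||
      c_eq < 0) {
    stop("`c_eq` must be a single non-negative number", call. = FALSE)
  }
  structure(list(d_eff = d_eff, k = k, c_eq = c_eq),
            class = "transport_params")
}

#' Finite-difference discretization
#'
#' Defaults follow the reference configuration for a 5 mm gel: 31 nodes give
#' a spatial step of L/30 (0.1667 mm for L = 5 mm) and the time step is
#' 300 s. Crank-Nicolson is unconditionally stable, so `dt` only controls
#' accuracy; a coarse `dt` relative to the diffusion time scale triggers a
#' warning, never an error.
#'
#' @param n_nodes Number of spatial nodes (>= 3); the grid spacing is
#'   `height / (n_nodes - 1)`.
#' @param dt Time step in seconds.
#' @return An object of class `discretization`.
#' @examples
#' discretization()            # 31 nodes, dt = 300 s
#' discretization(301, dt = 30)  # 10x refinement
#' @export
discretization <- function(n_nodes = 31L, dt = 300) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || !is.finite(n_nodes) ||
      n_nodes < 3 || n_nodes != round(n_nodes)) {
    stop("`n_nodes` must be a single integer >= 3", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  }
  structure(list(n_nodes = as.integer(n_nodes), dt = dt),
            class = "discretization")
}

#' Axial concentration profile
#'
#' @param z Ordered axial positions in metres, from 0 (sealed base) to L
#'   (release surface).
#' @param c Concentration at each position.
#' @param t Simulation time in seconds.
#' @return An object of class `concentration_profile`.
#' @export
concentration_profile <- function(z, c, t = 0) {
  if (length(z) != length(c)) {
    stop("`z` and `c` must have equal length", call. = FALSE)
  }
  if (is.unsorted(z, strictly = TRUE)) {
    stop("`z` must be strictly increasing", call. = FALSE)
  }
  structure(list(z = as.numeric(z), c = as.numeric(c), t = as.numeric(t)),
            class = "concentration_profile")
}

#' Cumulative release curve
#'
#' The central exchange object of the pipeline: cumulative released mass
#' and its percentage of the initial loading at a set of observation times.
#'
#' @param times Observation times in hours, non-decreasing.
#' @param cumulative_mass Released mass at each time (micrograms).
#' @param m_infinity Initial loaded mass M-infinity (micrograms).
#' @return An object of class `release_curve`, a list with elements
#'   `times`, `cumulative_mass`, `cumulative_percent` and `m_infinity`.
#' @export
release_curve <- function(times, cumulative_mass, m_infinity) {
  times <- as.numeric(times)
  cumulative_mass <- as.numeric(cumulative_mass)
  if (length(times) != length(cumulative_mass)) {
    stop("`times` and `cumulative_mass` must have equal length",
         call. = FALSE)
  }
  if (is.unsorted(times)) {
    stop("`times` must be non-decreasing", call. = FALSE)
  }
  if (!is.numeric(m_infinity) || length(m_infinity) != 1L || m_infinity <= 0) {
    stop("`m_infinity` must be a single positive mass", call. = FALSE)
  }
  structure(list(times = times,
                 cumulative_mass = cumulative_mass,
                 cumulative_percent = 100 * cumulative_mass / m_infinity,
                 m_infinity = m_infinity),
            class = "release_curve")
}

#' Per-interval supernatant measurements
#'
#' In the static protocol the complete supernatant is replaced at each
#' sampling time, so the measured quantity is the mass released during each
#' interval, not the running total.
#'
#' @param times Collection times in hours, strictly increasing.
#' @param masses Mass released in each interval (micrograms), non-negative.
#' @param m_initial Initially loaded mass (micrograms).
#' @return An object of class `supernatant_series`.
#' @export
supernatant_series <- function(times, masses, m_initial) {
  times <- as.numeric(times)
  masses <- as.numeric(masses)
  if (length(times) != length(masses)) {
    stop("`times` and `masses` must have equal length", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(masses < 0)) {
    stop("`masses` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(m_initial) || length(m_initial) != 1L || m_initial <= 0) {
    stop("`m_initial` must be a single positive mass", call. = FALSE)
  }
  structure(list(times = times, masses = masses, m_initial = m_initial),
            class = "supernatant_series")
}

#' @export
print.release_curve <- function(x, ...) {
  cat(sprintf(
    "<release_curve> %d time points, %.3g to %.3g h; final release %.2f%% of %.4g ug\n",
    length(x$times), min(x$times), max(x$times),
    x$cumulative_percent[length(x$cumulative_percent)], x$m_infinity))
  invisible(x)
}

#' @export
print.transport_params <- function(x, ...) {
  cat(sprintf("<transport_params> d_eff = %.4g m^2/s, k = %.4g m/s, c_eq = %.4g\n",
              x$d_eff, x$k, x$c_eq))
  invisible(x)
}

as_transport_params <- function(x) {
  if (inherits(x, "transport_params")) return(x)
  transport_params(x$d_eff, x$k, x$c_eq)
}
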