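# Build the Crank-Nicolson propagator for the axial diffusion model.
#
# Semi-discrete system dC/dt = A C + b on n nodes with spacing dz:
#   node 1 (sealed base): ghost node C_{-1} = C_1 (zero flux)
#   node n (release surface): ghost node from the Robin flux balance
#     -D dC/dz|_L = k (C_L - c_eq)
# Both boundaries use second-order centred ghost-node forms so the scheme
# stays O(dz^2) overall. Crank-Nicolson gives
#   (I - dt/2 A) C^{m+1} = (I + dt/2 A) C^m + dt b ,
# and since A is time-invariant the step reduces to C <- P C + q with P, q
# precomputed once per parameter set.
cn_system <- function(geometry, params, disc) {
  n <- disc$n_nodes
  dz <- geometry$height / (n - 1)
  r <- params$d_eff / dz^2
  A <- matrix(0, n, n)
  A[1L, 1L] <- -2 * r
  A[1L, 2L] <- 2 * r
  if (n > 2L) {
    idx <- 2L:(n - 1L)
    A[cbind(idx, idx - 1L)] <- r
    A[cbind(idx, idx)] <- -2 * r
    A[cbind(idx, idx + 1L)] <- r
  }
  A[n, n - 1L] <- 2 * r
  A[n, n] <- -2 * r - 2 * params$k / dz
  b <- numeric(n)
  b[n] <- 2 * params$k * params$c_eq / dz
  M1 <- diag(n) - disc$dt / 2 * A
  M2 <- diag(n) + disc$dt / 2 * A
  P <- tryCatch(solve(M1, M2),
                error = function(e) stop("Crank-Nicolson system is singular: ",
                                         conditionMessage(e), call. = FALSE))
  q <- solve(M1, disc$dt * b)
  # implicit-Euler half-step operator for the Rannacher startup: the first
  # two CN steps are replaced by four backward-Euler half-steps, which
  # damps the near-(-1) eigenmode the stiff Robin row excites on the
  # discontinuous initial data (surface ringing) while preserving global
  # second-order accuracy; backward Euler is also positivity-preserving
  # (M-matrix), so concentrations stay non-negative.
  Mbe <- diag(n) - disc$dt / 2 * A
  P_be <- solve(Mbe)
  q_be <- drop(P_be %*% (disc$dt / 2 * b))
  list(P = P, q = q, P_be = P_be, q_be = q_be, dz = dz,
       z = seq(0, geometry$height, length.out = n),
       w = dz * c(0.5, rep(1, n - 2L), 0.5))  # trapezoid weights
}

# number of initial full steps integrated by backward-Euler half-steps
RANNACHER_STEPS <- 2L

check_dt_accuracy <- function(geometry, params, disc) {
  # CN is unconditionally stable; warn only when dt is coarse relative to
  # the bulk diffusion time L^2 / D (accuracy, not stability).
  t_diff <- geometry$height^2 / params$d_eff
  if (disc$dt > 0.05 * t_diff) {
    warning(sprintf(
      "dt = %g s exceeds 5%% of the diffusion time L^2/D = %.3g s; ",
      disc$dt, t_diff),
      "Crank-Nicolson remains stable but temporal accuracy may suffer",
      call. = FALSE)
  }
  invisible(disc$dt / t_diff)
}

#' Advance the concentration profile by one Crank-Nicolson step
#'
#' One implicit time step of the axial diffusion model: interior nodes use
#' the trapezoidal (theta = 1/2) average of explicit and implicit second
#' differences; the sealed base and the Robin release surface enter through
#' second-order ghost-node rows.
#'
#' @param profile A [concentration_profile()] defined on the discretization
#'   grid.
#' @param params A [transport_params()] object.
#' @param geometry A [hydrogel_geometry()] object.
#' @param disc A [discretization()] object whose grid matches `profile`.
#' @return The profile advanced by `disc$dt` seconds.
#' @examples
#' geom <- hydrogel_geometry()
#' par <- transport_params(d_eff = 1e-9, k = 4e-5, c_eq = 0)
#' dis <- discretization()
#' p0 <- concentration_profile(seq(0, geom$height, length.out = 31), rep(1, 31))
#' p1 <- crank_nicolson_step(p0, par, geom, dis)
#' @export
crank_nicolson_step <- function(profile, params, geometry, disc) {
  params <- as_transport_params(params)
  sys <- cn_system(geometry, params, disc)
  if (length(profile$z) != disc$n_nodes ||
      max(abs(profile$z - sys$z)) > 1e-9 * geometry$height) {
    stop("`profile` is not defined on the discretization grid",
         call. = FALSE)
  }
  c_new <- drop(sys$P %*% profile$c) + sys$q
  concentration_profile(profile$z, c_new, profile$t + disc$dt)
}

#' Simulate solute release from a hydrogel cylinder
#'
#' Solves the one-dimensional diffusion equation
#' \eqn{\partial C/\partial t = D_{eff}\, \partial^2 C/\partial z^2} on
#' \eqn{z \in [0, L]} with a uniform initial concentration, zero flux at the
#' base (\eqn{z = 0}) and the interaction-limited Robin condition
#' \eqn{-D_{eff}\,\partial C/\partial z|_L = k\,(C|_L - C_{eq})} at the
#' release surface, by Crank-Nicolson finite differences. Released mass at
#' time t is \eqn{M_t = M_\infty - \pi R^2 \int_0^L C\,dz} with the integral
#' evaluated by the trapezoidal rule on the grid; values at observation
#' times falling between integration steps are linearly interpolated.
#'
#' Units are strictly SI internally (m, s); `c_initial` may be in any
#' concentration unit, and masses come out in that unit times m^3. Use
#' [ug_per_ml()] to express micrograms-per-millilitre loadings so that
#' cumulative masses are in micrograms.
#'
#' @param geometry A [hydrogel_geometry()].
#' @param params A [transport_params()].
#' @param c_initial Uniform initial concentration in the gel (same units as
#'   `params$c_eq`); must be non-negative.
#' @param disc A [discretization()].
#' @param obs_times Sorted non-negative observation times in hours.
#' @return A list with elements `curve` (a [release_curve()]; the attribute
#'   `"flux_mass"` carries the independently time-integrated Robin boundary
#'   flux at the observation times, for mass-balance verification) and
#'   `profiles` (a list of [concentration_profile()] objects, one per
#'   observation time).
#' @examples
#' res <- solve_release(hydrogel_geometry(),
#'                      transport_params(1.04e-9, 4.13e-5, 0),
#'                      c_initial = ug_per_ml(0.4), discretization(),
#'                      obs_times = c(0, 1, 6, 24))
#' res$curve
#' @export
solve_release <- function(geometry, params, c_initial, disc, obs_times) {
  params <- as_transport_params(params)
  if (!inherits(geometry, "hydrogel_geometry")) {
    geometry <- hydrogel_geometry(geometry$radius, geometry$height)
  }
  if (!inherits(disc, "discretization")) {
    disc <- discretization(disc$n_nodes, disc$dt)
  }
  if (!is.numeric(c_initial) || length(c_initial) != 1L || c_initial < 0) {
    stop("`c_initial` must be a single non-negative concentration",
         call. = FALSE)
  }
  obs_times <- as.numeric(obs_times)
  if (any(obs_times < 0) || is.unsorted(obs_times)) {
    stop("`obs_times` must be sorted and non-negative (hours)", call. = FALSE)
  }
  check_dt_accuracy(geometry, params, disc)

  sys <- cn_system(geometry, params, disc)
  area <- pi * geometry$radius^2
  m_inf <- c_initial * area * geometry$height
  obs_s <- obs_times * 3600
  dt <- disc$dt
  n_steps <- max(1L, as.integer(ceiling(max(obs_s) / dt - 1e-9)))

  gel_mass <- function(C) area * sum(sys$w * C)
  flux <- function(C) params$k * (C[length(C)] - params$c_eq) * area

  C <- rep(c_initial, disc$n_nodes)
  mt <- numeric(n_steps + 1L)          # released mass at step edges
  fx <- numeric(n_steps + 1L)          # time-integrated boundary flux
  mt[1L] <- m_inf - gel_mass(C)
  prev_flux <- flux(C)
  neg_tol <- -1e-12 * max(c_initial, params$c_eq, 1e-300)

  # profiles at observation times, linearly interpolated between steps
  profs <- vector("list", length(obs_s))
  obs_step <- obs_s / dt               # fractional step index of each time
  fill_obs <- function(i, C_prev, C_curr, step) {
    # observation i falls in (step-1, step]; interpolate
    w <- obs_step[i] - (step - 1L)
    concentration_profile(sys$z, (1 - w) * C_prev + w * C_curr, obs_s[i])
  }
  done <- obs_step <= 1e-9
  for (i in which(done)) {
    profs[[i]] <- concentration_profile(sys$z, C, 0)
  }

  for (s in seq_len(n_steps)) {
    C_prev <- C
    if (s <= RANNACHER_STEPS) {
      # two backward-Euler half-steps; backward Euler balances mass with
      # the implicit (right) endpoint, so the flux integral uses the
      # right-endpoint rule here and the trapezoid on later CN steps --
      # matching each scheme's own discrete conservation law
      C_mid <- drop(sys$P_be %*% C) + sys$q_be
      f_mid <- flux(C_mid)
      C <- drop(sys$P_be %*% C_mid) + sys$q_be
      f <- flux(C)
      fx[s + 1L] <- fx[s] + dt / 2 * (f_mid + f)
      prev_flux <- f
      mt[s + 1L] <- m_inf - gel_mass(C)
      if (any(C < neg_tol)) {
        stop("negative concentration produced by the solver; ",
             "this indicates invalid parameters or a solver bug",
             call. = FALSE)
      }
      hit <- !done & obs_step <= s + 1e-9
      for (i in which(hit)) profs[[i]] <- fill_obs(i, C_prev, C, s)
      done <- done | hit
      next
    }
    C <- drop(sys$P %*% C) + sys$q
    if (any(C < neg_tol)) {
      stop("negative concentration produced by the solver; ",
           "this indicates invalid parameters or a solver bug",
           call. = FALSE)
    }
    mt[s + 1L] <- m_inf - gel_mass(C)
    f <- flux(C)
    fx[s + 1L] <- fx[s] + dt * (prev_flux + f) / 2
    prev_flux <- f
    hit <- !done & obs_step <= s + 1e-9
    for (i in which(hit)) {
      profs[[i]] <- fill_obs(i, C_prev, C, s)
    }
    done <- done | hit
  }

  step_t <- (0:n_steps) * dt
  mass_obs <- stats::approx(step_t, mt, xout = obs_s, rule = 2)$y
  flux_obs <- stats::approx(step_t, fx, xout = obs_s, rule = 2)$y
  curve <- release_curve(obs_times, mass_obs, m_inf)
  attr(curve, "flux_mass") <- flux_obs
  list(curve = curve, profiles = profs)
}

#' Released mass from a concentration profile
#'
#' Computes \eqn{M_t = M_\infty - \pi R^2 \int_0^L C(z)\,dz} with the
#' integral evaluated by the trapezoidal rule over the profile grid.
#'
#' @param profile A [concentration_profile()] spanning `[0, height]`.
#' @param geometry A [hydrogel_geometry()].
#' @param m_infinity Initial loaded mass (same mass unit as the product of
#'   the concentration unit and m^3).
#' @return The released mass at the profile's time.
#' @export
cumulative_mass <- function(profile, geometry, m_infinity) {
  z <- profile$z
  if (abs(z[1L]) > 1e-12 * geometry$height ||
      abs(z[length(z)] - geometry$height) > 1e-9 * geometry$height) {
    stop("`profile` must span [0, height]", call. = FALSE)
  }
  integral <- sum(diff(z) * (profile$c[-1L] + profile$c[-length(z)]) / 2)
  mt <- m_infinity - pi * geometry$radius^2 * integral
  if (mt < -1e-8 * m_infinity) {
    stop("mass balance violated: released mass is negative ",
         "beyond numerical tolerance (solver bug?)", call. = FALSE)
  }
  mt
}

#' Analytic release fraction (eigenfunction-series oracle)
#'
#' Separation-of-variables solution for a slab insulated at z = 0 with a
#' Robin condition at z = L: eigenvalues \eqn{\beta_m} solve the
#' transcendental equation \eqn{\beta \tan\beta = Bi} with Biot number
#' \eqn{Bi = k L / D_{eff}}, and the fraction of the releasable mass
#' \eqn{M_\infty - \pi R^2 L\, C_{eq}} released by time t is
#' \deqn{1 - \sum_m \frac{2 \sin^2\beta_m}{\beta_m(\beta_m +
#'   \sin\beta_m\cos\beta_m)} \exp(-\beta_m^2 D_{eff} t / L^2).}
#' Serves as an independent closed-form oracle for the finite-difference
#' solver; it shares no code with it.
#'
#' @param params A [transport_params()] with `k > 0`.
#' @param geometry A [hydrogel_geometry()].
#' @param c_initial Uniform initial concentration (only its positivity
#'   matters; the released fraction is independent of the scale).
#' @param t Times in seconds (vectorised).
#' @param tol Series truncation tolerance on the remaining-fraction sum.
#' @param max_terms Maximum number of eigenmodes.
#' @return Released fraction(s) in `[0, 1]`, monotone in `t`.
#' @export
analytic_release_fraction <- function(params, geometry, c_initial, t,
                                      tol = 1e-10, max_terms = 500L) {
  params <- as_transport_params(params)
  if (params$k <= 0) {
    stop("`k` must be positive for the analytic series", call. = FALSE)
  }
  if (any(t < 0)) stop("`t` must be non-negative (seconds)", call. = FALSE)
  L <- geometry$height
  Bi <- params$k * L / params$d_eff
  beta <- robin_eigenvalues(Bi, max_terms)
  coef <- 2 * sin(beta)^2 / (beta * (beta + sin(beta) * cos(beta)))
  tau <- params$d_eff * t / L^2
  out <- vapply(tau, function(tt) {
    if (tt == 0) return(0)
    terms <- coef * exp(-beta^2 * tt)
    keep <- cumsum(abs(terms) < tol) == 0  # drop once terms fall under tol
    used <- terms[keep | seq_along(terms) <= 5L]
    if (length(used) == length(terms) &&
        abs(terms[length(terms)]) > tol) {
      warning("eigenfunction series not converged to tol within max_terms",
              call. = FALSE)
    }
    1 - sum(used)
  }, numeric(1))
  pmin(pmax(out, 0), 1)
}

# Roots of beta * tan(beta) = Bi; one root per interval
# ((m-1) pi, (m-1) pi + pi/2) for Bi > 0. Uses f = beta sin(beta) -
# Bi cos(beta), which changes sign across each interval without the tan
# singularity.
robin_eigenvalues <- function(Bi, n_roots) {
  f <- function(b) b * sin(b) - Bi * cos(b)
  vapply(seq_len(n_roots), function(m) {
    lo <- (m - 1) * pi + 1e-12
    hi <- (m - 1) * pi + pi / 2 - 1e-12
    stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  }, numeric(1))
}

# Fast evaluation of the Crank-Nicolson cumulative release percent at
# arbitrary observation times, via the spectral decomposition of the CN
# propagator. The semi-discrete operator A is similar to a symmetric
# tridiagonal matrix through the diagonal scaling s = (1, sqrt(2), ...,
# sqrt(2), 1) (the boundary rows carry factor-2 ghost-node entries), so its
# eigenproblem is solved with the guaranteed-real symmetric routine and the
# CN step eigenvalues follow as (1 + dt/2 lambda) / (1 - dt/2 lambda).
# Masses at the integer steps bracketing each observation time are combined
# by the same linear interpolation solve_release() uses, so the two paths
# agree to roundoff; this one costs one small eigendecomposition instead of
# thousands of time steps, which matters inside the genetic algorithm.
cn_release_percent <- function(geometry, params, c_initial, disc,
                               obs_times) {
  n <- disc$n_nodes
  if (params$k == 0 || c_initial == 0) {
    return(rep(0, length(obs_times)))
  }
  L <- geometry$height
  dz <- L / (n - 1)
  r <- params$d_eff / dz^2
  a <- disc$dt / 2
  As <- matrix(0, n, n)
  diag(As) <- c(rep(-2 * r, n - 1L), -2 * r - 2 * params$k / dz)
  off <- c(r * sqrt(2), rep(r, max(0L, n - 3L)), r * sqrt(2))[seq_len(n - 1L)]
  As[cbind(1:(n - 1L), 2:n)] <- off
  As[cbind(2:n, 1:(n - 1L))] <- off
  s <- c(1, rep(sqrt(2), n - 2L), 1)
  eg <- eigen(As, symmetric = TRUE)
  lam_cn <- (1 + a * eg$values) / (1 - a * eg$values)
  lam_be <- 1 / (1 - a * eg$values)   # backward-Euler half-step (h = dt/2)
  # per-mode gain after m full steps, with the Rannacher startup (each of
  # the first RANNACHER_STEPS full steps is two backward-Euler half-steps)
  mode_gain <- function(m) {
    m_start <- min(m, RANNACHER_STEPS)
    lam_be^(2 * m_start) * lam_cn^(m - m_start)
  }
  # steady state is uniform c_eq; project the scaled initial deviation
  y0 <- s * (c_initial - params$c_eq)
  wq <- drop(crossprod(eg$vectors, y0))
  w_trap <- dz * c(0.5, rep(1, n - 2L), 0.5)
  step_frac <- obs_times * 3600 / disc$dt
  steps <- sort(unique(c(floor(step_frac), ceiling(step_frac))))
  pct_at <- vapply(steps, function(m) {
    Cm <- drop(eg$vectors %*% (mode_gain(m) * wq)) / s + params$c_eq
    100 * sum(w_trap * (c_initial - Cm)) / (c_initial * L)
  }, numeric(1))
  lo <- floor(step_frac)
  hi <- ceiling(step_frac)
  wt <- step_frac - lo
  (1 - wt) * pct_at[match(lo, steps)] + wt * pct_at[match(hi, steps)]
}

#' Long-time release plateau
#'
#' The asymptotic cumulative release percentage of the Robin-surface model:
#' release stops when the gel equilibrates uniformly at `c_eq`, so the
#' plateau is \eqn{100\,(1 - C_{eq}/C_{initial})}. Matches the t -> infinity
#' limit of [solve_release()] whenever `k > 0`.
#'
#' @param params A [transport_params()].
#' @param c_initial Uniform initial concentration, > 0.
#' @return Plateau release percentage in `[0, 100]` (for
#'   `c_eq <= c_initial`).
#' @examples
#' plateau_percent(transport_params(1e-9, 4e-5, c_eq = 0.5393), c_initial = 1)
#' @export
plateau_percent <- function(params, c_initial) {
  params <- as_transport_params(params)
  if (!is.numeric(c_initial) || length(c_initial) != 1L || c_initial <= 0) {
    stop("`c_initial` must be a single positive concentration",
         call. = FALSE)
  }
  100 * (1 - params$c_eq / c_initial)
}

#' Calibrate the pseudo-equilibrium concentration from an observed plateau
#'
#' Inverts the plateau relation: a long-time cumulative release of
#' `plateau_pct` percent implies
#' \eqn{C_{eq} = C_{initial}(1 - plateau/100)}.
#'
#' @param plateau_pct Observed long-time cumulative release percentage.
#' @param c_initial Initial concentration.
#' @return The implied `c_eq`, same units as `c_initial`.
#' @export
c_eq_from_plateau <- function(plateau_pct, c_initial) {
  if (plateau_pct < 0 || plateau_pct > 100) {
    stop("`plateau_pct` must be in [0, 100]", call. = FALSE)
  }
  c_initial * (1 - plateau_pct / 100)
}

#' Convert a concentration from micrograms per millilitre to SI-consistent
#' units
#'
#' The solver works in metres, so a concentration in ug/mL must be scaled
#' to ug/m^3 (factor 1e6) for cumulative masses to come out in micrograms.
#'
#' @param x Concentration in micrograms per millilitre.
#' @return Concentration in micrograms per cubic metre.
#' @export
ug_per_ml <- function(x) x * 1e6
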