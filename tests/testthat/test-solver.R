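test_that("equilibrium and sealed gels release nothing", {
  ci <- ug_per_ml(0.4)
  # initial state already at the pseudo-equilibrium concentration
  eq <- solve_release(ref_geom, transport_params(1e-9, 4e-5, c_eq = ci),
                      ci, ref_disc, c(0, 1, 6, 24))
  expect_equal(eq$curve$cumulative_percent, rep(0, 4), tolerance = 1e-10)
  # k = 0 seals the release surface
  sealed <- solve_release(ref_geom, transport_params(1e-9, k = 0, c_eq = 0),
                          ci, ref_disc, c(0, 1, 6, 24))
  expect_equal(sealed$curve$cumulative_percent, rep(0, 4), tolerance = 1e-10)
})

test_that("trapezoidal mass reduction matches closed forms", {
  n <- 31L
  z <- seq(0, ref_geom$height, length.out = n)
  area <- pi * ref_geom$radius^2
  c0 <- 7.3
  m_inf <- c0 * area * ref_geom$height

  uniform <- concentration_profile(z, rep(c0, n))
  expect_lt(abs(cumulative_mass(uniform, ref_geom, m_inf)), 1e-12 * m_inf)

  empty <- concentration_profile(z, rep(0, n))
  expect_equal(cumulative_mass(empty, ref_geom, m_inf), m_inf)

  # linear profile: the trapezoid rule is exact, integral = c0 L / 2
  linear <- concentration_profile(z, c0 * z / ref_geom$height)
  expect_equal(cumulative_mass(linear, ref_geom, m_inf),
               m_inf - area * c0 * ref_geom$height / 2,
               tolerance = 1e-12)

  # a profile integrating to more than m_inf signals a solver bug
  expect_error(cumulative_mass(uniform, ref_geom, m_inf / 2),
               "mass balance")
})

test_that("a Crank-Nicolson step preserves uniform steady states", {
  z <- seq(0, ref_geom$height, length.out = 31)
  # sealed gel: any uniform profile is stationary
  p <- concentration_profile(z, rep(5, 31))
  p1 <- crank_nicolson_step(p, transport_params(1e-9, 0, 0), ref_geom,
                            ref_disc)
  expect_equal(p1$c, p$c, tolerance = 1e-12)
  expect_equal(p1$t, ref_disc$dt)
  # open gel at equilibrium: uniform c_eq is stationary
  peq <- concentration_profile(z, rep(2.5, 31))
  p2 <- crank_nicolson_step(peq, transport_params(1e-9, 4e-5, c_eq = 2.5),
                            ref_geom, ref_disc)
  expect_equal(p2$c, peq$c, tolerance = 1e-12)
})

test_that("Crank-Nicolson stepping is second-order in time", {
  par <- params_at_biot(1)
  b1 <- 0.86033358901938  # first root of beta tan(beta) = 1
  z <- seq(0, ref_geom$height, length.out = 31)
  p0 <- concentration_profile(z, cos(b1 * z / ref_geom$height))
  t_end <- 2400
  run <- function(dt) {
    p <- p0
    for (s in seq_len(t_end / dt)) {
      p <- crank_nicolson_step(p, par, ref_geom, discretization(31L, dt))
    }
    p$c
  }
  u <- lapply(c(150, 75, 37.5), run)
  ratio <- max(abs(u[[1]] - u[[2]])) / max(abs(u[[2]] - u[[3]]))
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.5)
})

test_that("release error shrinks quadratically in space and time", {
  ci <- ug_per_ml(0.4)
  release_at_6h <- function(disc) {
    suppressWarnings(
      solve_release(ref_geom, params_at_biot(10), ci, disc,
                    c(0, 6))$curve$cumulative_percent[2]
    )
  }
  # temporal refinement at fixed fine grid
  r_t <- vapply(c(1200, 600, 300, 150), function(dt) {
    release_at_6h(discretization(121L, dt))
  }, numeric(1))
  ratio_t <- (r_t[2] - r_t[3]) / (r_t[3] - r_t[4])
  expect_gt(ratio_t, 3.5)
  expect_lt(ratio_t, 4.5)
  # spatial refinement at fixed fine dt; dz halves 16 -> 31 -> 61
  r_s <- vapply(c(16L, 31L, 61L), function(n) {
    release_at_6h(discretization(n, 30))
  }, numeric(1))
  ratio_s <- (r_s[1] - r_s[2]) / (r_s[2] - r_s[3])
  expect_gt(ratio_s, 3.5)
  expect_lt(ratio_s, 4.5)
})

test_that("discrete maximum principle and monotone release hold", {
  ci <- ug_per_ml(1)
  set.seed(11)
  for (i in 1:5) {
    par <- transport_params(10^stats::runif(1, -10, -8.5),
                            10^stats::runif(1, -6.5, -4.5),
                            c_eq = stats::runif(1, 0, 0.9) * ci)
    res <- solve_release(ref_geom, par, ci, ref_disc, static_schedule)
    expect_true(all(diff(res$curve$cumulative_percent) >= -1e-10))
    for (p in res$profiles) {
      expect_true(all(p$c >= par$c_eq - 1e-6 * ci))
      expect_true(all(p$c <= ci + 1e-6 * ci))
    }
  }
})

test_that("profile integrals reproduce the reported curve masses", {
  ci <- ug_per_ml(0.4)
  res <- solve_release(ref_geom, params_at_biot(10), ci, ref_disc,
                       c(0, 0.5, 1, 3, 7, 26))
  m_from_profiles <- vapply(res$profiles, cumulative_mass, numeric(1),
                            geometry = ref_geom,
                            m_infinity = res$curve$m_infinity)
  expect_equal(m_from_profiles, res$curve$cumulative_mass,
               tolerance = 1e-10)
})

test_that("time-integrated boundary flux matches the released mass", {
  ci <- ug_per_ml(0.4)
  for (bi in c(1, 100)) {
    res <- solve_release(ref_geom, params_at_biot(bi), ci, ref_disc,
                         static_schedule)
    rel_err <- max(abs(attr(res$curve, "flux_mass") -
                         res$curve$cumulative_mass)) /
      res$curve$m_infinity
    expect_lt(rel_err, 0.005)
    res_f <- solve_release(ref_geom, params_at_biot(bi), ci, fine_disc,
                           c(0, 2, 8, 24))
    rel_err_f <- max(abs(attr(res_f$curve, "flux_mass") -
                           res_f$curve$cumulative_mass)) /
      res_f$curve$m_infinity
    expect_lt(rel_err_f, 5e-4)
  }
})

test_that("the spectral fast path agrees with the stepping solver", {
  ci <- ug_per_ml(0.8)
  for (bi in c(0.5, 50)) {
    par <- params_at_biot(bi, c_eq = 0.3 * ci)
    res <- solve_release(ref_geom, par, ci, ref_disc, static_schedule)
    fast <- relkin:::cn_release_percent(ref_geom, par, ci, ref_disc,
                                        static_schedule)
    expect_equal(fast, res$curve$cumulative_percent, tolerance = 1e-9)
  }
})

test_that("invalid inputs are rejected and coarse dt only warns", {
  expect_error(hydrogel_geometry(radius = -1), "radius")
  expect_error(transport_params(d_eff = 0, k = 1e-5), "d_eff")
  expect_error(transport_params(1e-9, k = -1), "k")
  expect_error(discretization(n_nodes = 2), "n_nodes")
  expect_error(solve_release(ref_geom, transport_params(1e-9, 1e-5), -1,
                             ref_disc, c(0, 1)), "c_initial")
  expect_error(solve_release(ref_geom, transport_params(1e-9, 1e-5), 1,
                             ref_disc, c(2, 1)), "sorted")
  expect_warning(
    solve_release(ref_geom, transport_params(1.04e-9, 1e-5), 1,
                  discretization(31L, 3600), c(0, 6)),
    "diffusion time")
})

test_that("long-time release settles at the analytic plateau", {
  ci <- ug_per_ml(0.4)
  par <- transport_params(1.04e-9, 4.13e-5, c_eq = 0.5 * ci)
  t_large <- 3.5 * ref_geom$height^2 / par$d_eff / 3600  # D t / L^2 = 3.5
  res <- solve_release(ref_geom, par, ci, ref_disc, c(0, t_large))
  expect_equal(res$curve$cumulative_percent[2],
               plateau_percent(par, ci), tolerance = 0.1 / 50)
})

test_that("plateau relation and its inverse are consistent", {
  expect_equal(plateau_percent(transport_params(1e-9, 1e-5, c_eq = 0), 1),
               100)
  expect_equal(plateau_percent(transport_params(1e-9, 1e-5, c_eq = 2), 2),
               0)
  ceq <- c_eq_from_plateau(46.07, ug_per_ml(0.4))
  expect_equal(plateau_percent(transport_params(1e-9, 1e-5, c_eq = ceq),
                               ug_per_ml(0.4)), 46.07)
  expect_error(plateau_percent(transport_params(1e-9, 1e-5), 0),
               "c_initial")
})
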