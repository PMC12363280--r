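# light GA settings: on noise-free data the simplex polish supplies the
# precision, the GA only needs to land in the right basin
light_ga <- function(seed, ...) {
  ga_config(population_size = 20L, generations = 15L, seed = seed, ...)
}

make_obs <- function(truth, c_initial) {
  solve_release(ref_geom, truth, c_initial, ref_disc, static_schedule)$curve
}

test_that("the objective is zero at truth and counts shifted points", {
  truth <- transport_params(1.40e-9, 1.190e-5, 0)
  ci <- ug_per_ml(1.6)
  obs <- make_obs(truth, ci)
  expect_lt(release_objective(truth, obs, ref_geom, ref_disc, ci), 1e-16)

  shifted <- release_curve(obs$times,
                           (obs$cumulative_percent + 1) / 100 *
                             obs$m_infinity, obs$m_infinity)
  expect_equal(release_objective(truth, shifted, ref_geom, ref_disc, ci),
               length(obs$times), tolerance = 1e-8)
})

test_that("the objective is locally identifying in d_eff", {
  truth <- transport_params(1.40e-9, 1.190e-5, 0)
  ci <- ug_per_ml(1.6)
  obs <- make_obs(truth, ci)
  up <- transport_params(truth$d_eff * 1.1, truth$k, 0)
  dn <- transport_params(truth$d_eff * 0.9, truth$k, 0)
  expect_gt(release_objective(up, obs, ref_geom, ref_disc, ci), 1e-4)
  expect_gt(release_objective(dn, obs, ref_geom, ref_disc, ci), 1e-4)
})

test_that("noise-free recovery hits truth within the documented bounds", {
  truth <- transport_params(1.40e-9, 1.190e-5, 0)  # Biot ~ 42, k visible
  ci <- ug_per_ml(1.6)
  obs <- make_obs(truth, ci)
  fit <- estimate_transport(obs, ref_geom, ref_disc, ci,
                            fixed = truth, config = light_ga(7))
  expect_lt(abs(fit$params$d_eff - truth$d_eff) / truth$d_eff, 0.05)
  expect_lt(abs(fit$params$k - truth$k) / truth$k, 0.10)
  expect_gt(fit$r_squared, 0.999)
})

test_that("identical seed and data reproduce the fit exactly", {
  truth <- transport_params(1.04e-9, 4.13e-5, 0)
  ci <- ug_per_ml(0.4)
  obs <- make_obs(truth, ci)
  f1 <- estimate_transport(obs, ref_geom, ref_disc, ci, fixed = truth,
                           config = light_ga(99))
  f2 <- estimate_transport(obs, ref_geom, ref_disc, ci, fixed = truth,
                           config = light_ga(99))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  f3 <- estimate_transport(obs, ref_geom, ref_disc, ci, fixed = truth,
                           config = light_ga(100))
  expect_false(identical(f3$history, f1$history))
})

test_that("best objective per generation never deteriorates", {
  truth <- transport_params(1.04e-9, 4.13e-5, 0)
  ci <- ug_per_ml(0.4)
  obs <- make_obs(truth, ci)
  fit <- estimate_transport(obs, ref_geom, ref_disc, ci, fixed = truth,
                            config = light_ga(5))
  expect_true(all(diff(fit$history) <= 1e-12))
})

test_that("collapsed bounds return the pinned point", {
  truth <- transport_params(1.04e-9, 4.13e-5, 0)
  ci <- ug_per_ml(0.4)
  obs <- make_obs(truth, ci)
  pin <- list(d_eff = c(2e-9, 2e-9), k = c(1e-5, 1e-5),
              c_eq_ratio = c(0, 1))
  fit <- estimate_transport(obs, ref_geom, ref_disc, ci, fixed = truth,
                            config = ga_config(bounds = pin, seed = 1,
                                               generations = 2))
  expect_equal(fit$params$d_eff, 2e-9, tolerance = 1e-12)
  expect_equal(fit$params$k, 1e-5, tolerance = 1e-12)
  expect_equal(fit$sse,
               release_objective(transport_params(2e-9, 1e-5, 0), obs,
                                 ref_geom, ref_disc, ci))
})

test_that("median noisy-replicate recovery of d_eff stays within 10%", {
  truth <- transport_params(1.04e-9, 4.13e-5, 0)
  ci <- ug_per_ml(0.4)
  clean <- make_obs(truth, ci)
  set.seed(314)
  d_hat <- vapply(1:12, function(i) {
    noisy_pct <- clean$cumulative_percent *
      (1 + stats::rnorm(length(clean$times), 0, 0.05))
    noisy <- release_curve(clean$times,
                           pmax(noisy_pct, 0) / 100 * clean$m_infinity,
                           clean$m_infinity)
    fit <- estimate_transport(noisy, ref_geom, ref_disc, ci,
                              fixed = truth, config = light_ga(i))
    fit$params$d_eff
  }, numeric(1))
  expect_lt(abs(stats::median(d_hat) - truth$d_eff) / truth$d_eff, 0.10)
})

test_that("objective profiles expose weak and strong directions", {
  truth <- transport_params(1.04e-9, 4.13e-5, 0)  # Biot ~ 200: k is flat
  ci <- ug_per_ml(0.4)
  obs <- make_obs(truth, ci)
  expect_warning(
    pk <- profile_objective(obs, ref_geom, ref_disc, ci, "k",
                            grid = truth$k * c(0.5, 0.75, 1, 1.5, 2),
                            at = truth),
    "weakly identified")
  expect_equal(pk$objective[3], 0, tolerance = 1e-12)

  expect_no_warning(
    pd <- profile_objective(obs, ref_geom, ref_disc, ci, "d_eff",
                            grid = truth$d_eff * c(0.5, 0.75, 1, 1.5, 2),
                            at = truth))
  expect_equal(which.min(pd$objective), 3L)
  expect_true(all(pd$objective[-3] > 1))
})

test_that("configuration invariants are validated", {
  expect_error(ga_config(population_size = 5), "at least 10")
  expect_error(ga_config(crossover_rate = 1.5), "rates")
  expect_error(ga_config(bounds = list(d_eff = c(1e-8, 1e-12),
                                       k = c(1e-8, 1e-3))), "low <= high")
  truth <- transport_params(1e-9, 1e-5, 0)
  short <- release_curve(c(1, 2, 3), c(1, 2, 3), 100)
  expect_error(estimate_transport(short, ref_geom, ref_disc, 1,
                                  fixed = truth), "at least 4")
})
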