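test_that("water density reproduces the reference table", {
  expect_equal(water_density(4), 1.0000, tolerance = 2e-4)
  expect_equal(water_density(25), 0.99705, tolerance = 1e-4)
  # polynomial stays within 1e-4 g/mL of every bundled reference point
  tab <- relkin:::water_density_table()
  expect_lt(max(abs(water_density(tab$temperature_c) - tab$density_g_ml)),
            1e-4)
  # monotone decreasing above the density maximum
  grid <- seq(4, 80, by = 0.5)
  expect_true(all(diff(water_density(grid)) < 0))
  expect_error(water_density(-5), "0, 80")
  expect_error(water_density(90), "0, 80")
})

test_that("flow follows mass over density times duration", {
  # 1 g of unit-density water in 1 min -> 1 mL/min (near 4 C)
  expect_equal(flow_from_collection(1, 4, 1), 1, tolerance = 2e-4)
  expect_equal(flow_from_collection(0.12, 25, 60),
               0.12 / (0.99705 * 60), tolerance = 1e-4)
  # proportionality: tripling the duration divides the flow by 3
  expect_equal(flow_from_collection(0.5, 25, 30),
               3 * flow_from_collection(0.5, 25, 90))
  expect_error(flow_from_collection(1, 25, 0), "minutes")
})

test_that("pump calibration is exact on linear data and order-invariant", {
  rpms <- c(0.1, 0.5, 1, 5, 10)
  slope_true <- 0.004
  rho25 <- water_density(25)
  recs <- do.call(rbind, lapply(rpms, function(r) {
    data.frame(rpm = r, mass_g = slope_true * r * 30 * rho25,
               temperature_c = 25, minutes = 30)
  }))
  cal <- fit_pump_calibration(recs)
  expect_equal(cal$slope, slope_true, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)

  perm <- recs[sample.int(nrow(recs)), ]
  cal2 <- fit_pump_calibration(perm)
  expect_equal(cal2$slope, cal$slope)
  expect_equal(cal2$intercept, cal$intercept)

  expect_error(fit_pump_calibration(recs[recs$rpm == 1, ]),
               "two distinct RPM")
})

test_that("noisy calibration recovers the true slope", {
  set.seed(8)
  rpms <- rep(c(0.1, 0.5, 1, 5, 10), each = 3)
  slope_true <- 0.004
  recs <- data.frame(
    rpm = rpms,
    mass_g = slope_true * rpms * 60 * water_density(25) *
      (1 + stats::rnorm(length(rpms), 0, 0.02)),
    temperature_c = 25, minutes = 60)
  cal <- fit_pump_calibration(recs)
  expect_equal(cal$slope, slope_true, tolerance = 0.05)
  expect_gt(cal$r_squared, 0.99)
})

test_that("fraction bins accumulate into a right-edge-stamped curve", {
  fr <- fraction_series(3, c(0, 0, 1, 2, 1.5), m_initial = 10)
  cv <- cumulative_release_from_fractions(fr)
  expect_equal(cv$times, c(2, 4, 6, 8, 10))
  expect_equal(cv$cumulative_percent, c(0, 0, 10, 30, 45))

  zero <- fraction_series(3, rep(0, 4), 10)
  expect_equal(cumulative_release_from_fractions(zero)$cumulative_percent,
               rep(0, 4))

  near_all <- fraction_series(3, c(5, 4.5), 10)
  expect_equal(max(cumulative_release_from_fractions(near_all)$
                     cumulative_percent), 95)

  over <- fraction_series(3, c(6, 6), 10)
  expect_warning(cumulative_release_from_fractions(over), "above 100")
})

test_that("dead-volume delay rounds up to the collection grid", {
  # 300 uL at 0.5 uL/min is a 10 h raw delay, already on a 2-h edge
  expect_equal(dead_time(0.5, 300), 10)
  # zero dead volume: first possible detection is the first bin edge
  expect_equal(dead_time(3, 0), 2)
  # doubling the flow halves the raw delay before binning
  expect_equal(dead_time(1, 330) , 6)   # 5.5 h -> 6 h
  expect_equal(dead_time(2, 330), 4)    # 2.75 h -> 4 h
  # non-increasing in flow
  flows <- c(0.5, 1, 2, 3, 6.5, 10)
  expect_true(all(diff(dead_time(flows, 300)) <= 0))
  expect_error(dead_time(0, 300), "positive")
})

test_that("mass balance sums released and compartment percentages", {
  comp <- compartment_distribution(26.2, 5.4, 3.1, 6.6)
  expect_equal(mass_balance(58.7, comp), 100, tolerance = 1e-12)
  expect_equal(mass_balance(0, compartment_distribution(0, 100, 0, 0)),
               100)
  expect_equal(mass_balance(100, compartment_distribution(0, 0, 0, 0)),
               100)
  expect_warning(out <- mass_balance(58.7, compartment_distribution(
    20, 5, 3, 6)), "flagged")
  expect_equal(out, 92.7)
  expect_error(mass_balance(-1, comp), "non-negative")
})
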