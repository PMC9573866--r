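test_that("acid-fractionation adjustment only shifts the 72C automated line", {
  expect_equal(acid_fractionation_adjust(1.00, "auto72C"), 0.91)
  expect_equal(acid_fractionation_adjust(1.00, "micro25C"), 1.00)
  expect_equal(acid_fractionation_adjust(-0.33, "auto72C"), -0.42)
  expect_equal(acid_fractionation_adjust(c(1, 1), c("auto72C", "micro25C")),
               c(0.91, 1))
  expect_error(acid_fractionation_adjust(1, "gasbench"), "unknown instrument")
})

test_that("seawater d18O-salinity regression recovers exact and random fits", {
  s <- seq(33.0, 33.6, by = 0.05)
  d <- 0.279 * s - 9.63
  cal <- fit_sw_salinity_regression(s, d)
  expect_equal(cal$slope, 0.279, tolerance = 1e-9)
  expect_equal(cal$intercept, -9.63, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1)

  # two distinct points duplicated: exact line through them
  cal2 <- fit_sw_salinity_regression(c(33, 33, 34, 34), c(0, 0, 1, 1))
  expect_equal(cal2$slope, 1, tolerance = 1e-12)
  expect_equal(cal2$intercept, -33, tolerance = 1e-9)

  # random pairs against the normal-equations oracle
  set.seed(5)
  s3 <- runif(40, 32, 35)
  d3 <- 0.3 * s3 - 10 + rnorm(40, 0, 0.05)
  cal3 <- fit_sw_salinity_regression(s3, d3)
  beta <- ols_oracle(cbind(1, s3), d3)
  expect_equal(cal3$intercept, unname(beta[1]), tolerance = 1e-9)
  expect_equal(cal3$slope, unname(beta[2]), tolerance = 1e-9)

  expect_error(fit_sw_salinity_regression(rep(33, 5), rnorm(5)), "degenerate")
})

test_that("seawater d18O predictions reproduce printed salinity propagation", {
  ca <- sw_calibration_fixed("fixed-CA")
  expect_equal(round(sw_d18o_from_salinity(32.93, ca), 2), -0.44)
  expect_equal(round(sw_d18o_from_salinity(33.69, ca), 2), -0.23)
  ko <- sw_calibration_fixed("fixed-KO")
  expect_equal(sw_d18o_from_salinity(34.0, ko), -0.02, tolerance = 1e-9)
})

test_that("the aragonite fractionation line and its inverse are consistent", {
  expect_equal(forward_otolith_d18o(-0.5, 0), -0.5 + 2.69)
  expect_equal(forward_otolith_d18o(-0.32, 15), -0.33, tolerance = 1e-12)
  # strict linear decrease at -0.18 permil/degC
  tt <- seq(0, 30, by = 0.5)
  d <- forward_otolith_d18o(0, tt)
  expect_equal(diff(d) / 0.5, rep(-0.18, length(tt) - 1), tolerance = 1e-12)

  expect_equal(invert_fixed_sw(-0.32 + 2.69, -0.32), 0)
  expect_equal(invert_fixed_sw(-0.33, -0.32), 15, tolerance = 1e-12)
  # round trip over 0..30 degC
  expect_equal(invert_fixed_sw(forward_otolith_d18o(-0.32, tt), -0.32), tt,
               tolerance = 1e-12)
})

test_that("seawater d18O variation maps linearly to temperature error", {
  expect_equal(sw_variation_to_temp_error(0.12), 0.12 / 0.18)
  expect_lt(sw_variation_to_temp_error(0.12), 0.7)
  expect_equal(sw_variation_to_temp_error(0), 0)
  expect_equal(sw_variation_to_temp_error(0.18), 1)
  expect_error(sw_variation_to_temp_error(-0.1))
})

test_that("monthly thermometers reproduce temperature from implied d18O", {
  ko <- sw_calibration_fixed("fixed-KO")

  # fixed salinity: T is exactly linear in d18O, fit is exact
  obs <- data.frame(temp_c = seq(8, 24, by = 2), salinity = 34.0)
  th <- build_monthly_thermometer(obs, ko, month = 4)
  expect_lt(th$rmse, 1e-9)
  d12 <- forward_otolith_d18o(sw_d18o_from_salinity(34.0, ko), 12)
  expect_equal(invert_quadratic(d12, th), 12, tolerance = 1e-6)

  # tight linear T-S relation with 0.2 degC scatter: RMSE below 0.5 degC
  hyd <- gen_hydro(month = 5, n_obs = 300, ts_slope = 8,
                   ts_intercept = 15 - 8 * 33.5, scatter_sd = 0.2,
                   salinity_range = c(33.0, 34.0), seed = 11)
  th2 <- build_monthly_thermometer(hyd, ko)
  expect_lt(th2$rmse, 0.5)

  # coefficients equal the normal-equations quadratic oracle
  d <- forward_otolith_d18o(sw_d18o_from_salinity(hyd$salinity, ko),
                            hyd$temp_c)
  beta <- ols_oracle(cbind(1, d, d^2), hyd$temp_c)
  expect_equal(unname(th2$coef["c"]), unname(beta[1]), tolerance = 1e-8)
  expect_equal(unname(th2$coef["b"]), unname(beta[2]), tolerance = 1e-8)
  expect_equal(unname(th2$coef["a"]), unname(beta[3]), tolerance = 1e-8)

  expect_error(build_monthly_thermometer(obs[1:2, ], ko, month = 4),
               "at least 3")
})

test_that("quadratic inversion enforces the extrapolation margin", {
  ko <- sw_calibration_fixed("fixed-KO")
  obs <- data.frame(temp_c = seq(8, 24, by = 2), salinity = 34.0)
  th <- build_monthly_thermometer(obs, ko, month = 4)
  edge <- th$d18o_range[2]
  expect_warning(invert_quadratic(edge + 0.4, th), "outside validity")
  expect_error(invert_quadratic(edge + 0.6, th), "beyond validity")
  expect_silent(invert_quadratic(mean(th$d18o_range), th))
})

test_that("interval months come from the median deposition date", {
  expect_equal(assign_interval_month(as.Date("2008-03-01"), c(0, 30)), 3L)
  expect_equal(assign_interval_month(as.Date("2008-03-01"), c(31, 60)), 4L)
  # hatch 20 Mar, median day 15 -> 4 Apr
  expect_equal(assign_interval_month(as.Date("2008-03-20"), c(0, 30)), 4L)
})

test_that("thermal_history recovers per-interval temperatures on synthetics", {
  # fixed-seawater mode (CA): noise-free is exact
  p0 <- cohort_params("CA", n_fish = 3, ar1_sigma = 0,
                      iso_noise_d18o = 0, iso_noise_d13c = 0, seed = 8)
  coh0 <- gen_fish_cohort(p0)
  th0 <- thermal_history(coh0$isotopes, mode = "fixed", d18o_sw = -0.32)
  expect_equal(th0$temp_c, coh0$truth$intervals$t_mean_true, tolerance = 1e-9)

  # default noise (0.10 permil): per-interval RMSE at most 1.0 degC
  p1 <- cohort_params("CA", n_fish = 50, seed = 9)
  coh1 <- gen_fish_cohort(p1)
  th1 <- thermal_history(coh1$isotopes, mode = "fixed", d18o_sw = -0.32)
  rmse <- sqrt(mean((th1$temp_c - coh1$truth$intervals$t_mean_true)^2))
  expect_lte(rmse, 1.0)

  # monthly mode round trip on a fixed-salinity thermometer
  ko <- sw_calibration_fixed("fixed-KO")
  thermo <- list()
  for (m in 4:9) {
    thermo[[m]] <- build_monthly_thermometer(
      data.frame(temp_c = seq(6, 26, by = 1), salinity = 34.0), ko, month = m)
  }
  p2 <- cohort_params("JP", n_fish = 3, ar1_sigma = 0,
                      iso_noise_d18o = 0, iso_noise_d13c = 0,
                      jp_salinity = 34.0, seed = 10)
  coh2 <- gen_fish_cohort(p2)
  fish1 <- coh2$isotopes[coh2$isotopes$fish_id == coh2$isotopes$fish_id[1], ]
  th2 <- thermal_history(fish1, mode = "monthly",
                         hatch_date = coh2$fish$hatch_date[1],
                         thermometers = thermo)
  truth1 <- coh2$truth$intervals[
    coh2$truth$intervals$fish_id == fish1$fish_id[1], ]
  expect_equal(th2$temp_c, truth1$t_mean_true, tolerance = 1e-6)
  expect_true(all(th2$method == "monthly-quadratic"))
  expect_equal(th2$month[1], 4L)
})
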