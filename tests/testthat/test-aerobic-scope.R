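test_that("temperature binning drops sparse bins and matches percentile oracle", {
  # a 2-member bin is dropped, surrounded by full bins
  temps <- c(14.2, 14.9, rep(15.5, 5), rep(16.5, 5), rep(17.5, 5))
  moto <- seq_along(temps) / 20
  bins <- bin_by_temperature(temps, moto)
  expect_false(14.5 %in% bins$center)
  expect_equal(nrow(bins), 3)

  # degenerate percentiles: five identical values
  b2 <- bin_by_temperature(c(rep(15.5, 5), rep(16.5, 4), rep(17.5, 4)),
                           c(rep(0.3, 5), rnorm(4, 0.3, 0.01),
                             rnorm(4, 0.3, 0.01)))
  expect_equal(b2$p95[1], 0.3)
  expect_equal(b2$p5[1], 0.3)

  # random bin against the order-statistic interpolation oracle
  set.seed(21)
  x <- runif(37, 0.1, 0.5)
  t4 <- c(rep(15.5, 37), rep(16.5, 6), rep(17.5, 6))
  x4 <- c(x, runif(12))
  b4 <- bin_by_temperature(t4, x4)
  expect_equal(b4$p95[1], percentile_oracle(x, 0.95))
  expect_equal(b4$p5[1], percentile_oracle(x, 0.05))

  expect_error(bin_by_temperature(c(15.2, 15.3, 16.1), c(1, 2, 3)),
               "fewer than 3 retained bins")
})

test_that("upper envelope quadratic fit recovers exact and random cases", {
  centers <- seq(12.5, 19.5, by = 1)
  p95 <- 0.5 - 0.01 * (centers - 16)^2
  bins <- data.frame(bin_lo = centers - 0.5, center = centers,
                     n = 10, p95 = p95, p5 = 0.1)
  co <- fit_upper_envelope(bins)
  expect_equal(unname(co["c2"]), -0.01, tolerance = 1e-9)
  expect_equal(unname(co["c1"]), 0.32, tolerance = 1e-9)
  expect_equal(unname(co["c0"]), 0.5 - 2.56, tolerance = 1e-9)

  # 3 bins: interpolating quadratic with zero residual
  b3 <- bins[1:3, ]
  b3$p95 <- c(0.2, 0.5, 0.4)
  co3 <- fit_upper_envelope(b3)
  fitted <- co3["c0"] + co3["c1"] * b3$center + co3["c2"] * b3$center^2
  expect_equal(unname(fitted), b3$p95, tolerance = 1e-9)

  # noisy values against the normal-equations oracle
  set.seed(3)
  bins$p95 <- p95 + rnorm(8, 0, 0.01)
  cof <- fit_upper_envelope(bins)
  beta <- ols_oracle(cbind(1, bins$center, bins$center^2), bins$p95)
  expect_equal(unname(cof), unname(beta[c(1, 2, 3)]), tolerance = 1e-8)

  expect_error(fit_upper_envelope(bins[1:2, ]), "at least 3")
})

test_that("lower envelope log-link fit recovers exact and noisy cases", {
  centers <- seq(12.5, 19.5, by = 1)
  bins <- data.frame(center = centers, p5 = exp(0.1 + 0.05 * centers))
  eta <- fit_lower_envelope(bins)
  expect_equal(unname(eta), c(0.1, 0.05), tolerance = 1e-6)

  # two bins: exact interpolation through both points
  b2 <- bins[c(1, 8), ]
  eta2 <- fit_lower_envelope(b2)
  expect_equal(exp(eta2["eta0"] + eta2["eta1"] * b2$center),
               b2$p5, tolerance = 1e-6, ignore_attr = TRUE)

  # noisy values against a grid-search Gaussian-likelihood oracle
  set.seed(4)
  bins$p5 <- exp(0.1 + 0.05 * centers) + rnorm(8, 0, 0.01)
  eta3 <- fit_lower_envelope(bins)
  grid0 <- seq(eta3["eta0"] - 0.2, eta3["eta0"] + 0.2, length.out = 81)
  grid1 <- seq(eta3["eta1"] - 0.02, eta3["eta1"] + 0.02, length.out = 81)
  sse <- outer(grid0, grid1, Vectorize(function(e0, e1) {
    sum((bins$p5 - exp(e0 + e1 * bins$center))^2)
  }))
  best <- which(sse == min(sse), arr.ind = TRUE)[1, ]
  expect_equal(unname(eta3["eta0"]), grid0[best[1]],
               tolerance = 2 * diff(grid0[1:2]))
  expect_equal(unname(eta3["eta1"]), grid1[best[2]],
               tolerance = 2 * diff(grid1[1:2]))

  bins$p5[3] <- -0.01
  expect_error(fit_lower_envelope(bins), "inspect")
})

test_that("gap argmax locates the optimal temperature on the grid", {
  # flat lower bound: argmax is the quadratic's vertex at 16
  upper <- c(c0 = 0.5 - 0.002 * 256, c1 = 0.002 * 32, c2 = -0.002)
  lower <- c(eta0 = log(0.1), eta1 = 0)
  opt <- optimal_temperature(upper, lower, range = c(10, 20))
  expect_equal(opt$t_opt, 16.0)

  # monotone increasing gap: boundary argmax at 20
  up2 <- c(c0 = 0, c1 = 0.05, c2 = 0)
  opt2 <- optimal_temperature(up2, lower, range = c(10, 20))
  expect_equal(opt2$t_opt, 20.0)

  # nowhere-positive gap flags a warning
  up3 <- c(c0 = -1, c1 = 0, c2 = 0)
  expect_warning(opt3 <- optimal_temperature(up3, lower, c(10, 20)),
                 "nowhere positive")
  expect_true(opt3$all_nonpositive)
})

test_that("rescaling M_oto by a positive constant leaves t_opt unchanged", {
  set.seed(6)
  p <- cohort_params("JP", n_fish = 120, seed = 6)
  coh <- gen_fish_cohort(p)
  tt <- coh$truth$intervals$t_mean_true
  mm <- coh$truth$intervals$m_true
  env1 <- estimate_scope_envelope(tt, mm)
  env2 <- estimate_scope_envelope(tt, 3 * mm)
  expect_equal(env1$t_opt, env2$t_opt)
  # the gap rescales by the same constant
  expect_equal(env2$gap$gap, 3 * env1$gap$gap, tolerance = 1e-6)
  # t_opt always inside the occupied range
  expect_gte(env1$t_opt, env1$range[1])
  expect_lte(env1$t_opt, env1$range[2])
})

test_that("the envelope recovers the generator's optimal temperature", {
  errs <- vapply(1:5, function(s) {
    coh <- gen_fish_cohort(cohort_params("JP", n_fish = 300, seed = 400 + s))
    env <- estimate_scope_envelope(coh$truth$intervals$t_mean_true,
                                   coh$truth$intervals$m_true)
    abs(env$t_opt - coh$truth$t_opt_true)
  }, numeric(1))
  expect_lte(median(errs), 1.0)
})
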