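test_that("Ricker fit matches the hand OLS solution", {
  # S = (1,2,3), ln(R/S) = (1.0, 0.5, 0.3): slope -0.35, intercept 1.3
  ssb <- c(1, 2, 3)
  recruits <- ssb * exp(c(1.0, 0.5, 0.3))
  co <- fit_ricker(ssb, recruits)
  expect_equal(co[["a"]], 1.3, tolerance = 1e-9)
  expect_equal(co[["b"]], -0.35, tolerance = 1e-9)

  res <- lnrr(ssb, recruits, co)
  expect_equal(res, c(0.05, -0.10, 0.05), tolerance = 1e-9)
  expect_equal(sum(res), 0, tolerance = 1e-9)

  # exact Ricker data: zero residuals
  r2 <- c(2, 5, 9) * exp(0.8 - 0.1 * c(2, 5, 9))
  expect_lt(max(abs(lnrr(c(2, 5, 9), r2))), 1e-9)

  expect_error(fit_ricker(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(fit_ricker(c(1, -2, 3), c(1, 2, 3)), "positive")
})

test_that("LNRR from an internal fit always sums to zero", {
  for (s in 1:5) {
    g <- gen_stock_recruit(a = 1.2, b = -0.0008, temp_effect = 0.3,
                           sigma = 0.4, n_years = 40, seed = s)
    res <- lnrr(g$stock$ssb, g$stock$recruits)
    expect_lt(abs(sum(res)), 1e-9 * length(res))
  }
})

test_that("Ricker coefficients are recovered within 3 SE on synthetic series", {
  g <- gen_stock_recruit(a = 1.5, b = -0.001, temp_effect = 0, sigma = 0.3,
                         n_years = 100, seed = 17)
  co <- fit_ricker(g$stock$ssb, g$stock$recruits)
  fit <- summary(lm(log(g$stock$recruits / g$stock$ssb) ~ g$stock$ssb))
  se <- fit$coefficients[, "Std. Error"]
  expect_lt(abs(co[["a"]] - 1.5), 3 * se[1])
  expect_lt(abs(co[["b"]] - (-0.001)), 3 * se[2])
})

test_that("Pearson correlation matches the direct t-transform formula", {
  x <- c(1, 2, 3, 4, 5)
  res <- pearson_with_p(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-12)

  # orthogonal, mean-zero pair: r = 0, p = 1
  res0 <- pearson_with_p(c(-1, 0, 1), c(1, -2, 1))
  expect_equal(res0$r, 0)
  expect_equal(res0$p, 1)

  set.seed(12)
  a <- rnorm(10); b <- rnorm(10)
  res2 <- pearson_with_p(a, b)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  tstat <- r * sqrt((10 - 2) / (1 - r^2))
  expect_equal(res2$r, r, tolerance = 1e-12)
  expect_equal(res2$p, 2 * pt(-abs(tstat), 8), tolerance = 1e-12)

  expect_error(pearson_with_p(rep(1, 5), 1:5), "zero variance")
})

test_that("Benjamini-Hochberg step-up matches hand and brute-force results", {
  res <- bh_adjust(c(0.01, 0.02, 0.04, 0.5), alpha = 0.05)
  expect_equal(res$reject, c(TRUE, TRUE, FALSE, FALSE))

  expect_false(any(bh_adjust(rep(1, 5))$reject))
  expect_true(bh_adjust(0.01)$reject)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  # exhaustive small cases against the enumeration oracle
  set.seed(33)
  for (rep in 1:20) {
    p <- round(runif(6), 3)
    expect_equal(bh_adjust(p)$reject, bh_oracle_reject(p),
                 info = paste(p, collapse = ","))
  }
})

test_that("quadratic-term AIC selection prefers the right shape", {
  tt <- seq(10, 22, length.out = 30)
  # exactly linear: tie broken to fewer parameters
  lin <- quadratic_term_selection(3 + 2 * tt, tt)
  expect_equal(lin$chosen, "linear")

  # exact dome: quadratic with negative curvature
  dome <- quadratic_term_selection(-(tt - 16)^2, tt)
  expect_equal(dome$chosen, "quadratic")
  expect_lt(dome$coef[["I(temps^2)"]], 0)

  # noisy dome: same choice as the hand AIC oracle
  set.seed(14)
  y <- 50 - 0.8 * (tt - 16)^2 + rnorm(30, 0, 2)
  ch <- quadratic_term_selection(y, tt)
  aics <- c(null = aic_oracle(y, cbind(rep(1, 30))),
            linear = aic_oracle(y, cbind(1, tt)),
            quadratic = aic_oracle(y, cbind(1, tt, tt^2)))
  expect_equal(ch$chosen, names(which.min(aics)))
  expect_equal(unname(ch$aic), unname(aics), tolerance = 1e-9)

  expect_error(quadratic_term_selection(rnorm(10), rep(15, 10)), "degenerate")
})

test_that("AIC model choice is invariant to affine rescaling of temperature", {
  set.seed(15)
  tt <- seq(10, 22, length.out = 40)
  y <- 50 - 0.8 * (tt - 16)^2 + rnorm(40, 0, 2)
  a <- quadratic_term_selection(y, tt)
  b <- quadratic_term_selection(y, 1.8 * tt + 32)
  expect_equal(a$chosen, b$chosen)
  expect_equal(unname(a$aic), unname(b$aic), tolerance = 1e-6)
})

test_that("survival-anomaly correlation handles degenerate and exact cases", {
  g0 <- gen_stock_recruit(a = 1, b = -0.001, temp_effect = 0, sigma = 0,
                          n_years = 20, seed = 1)
  expect_error(correlate_survival_with_anomaly(g0$stock, g0$anomaly),
               "zero variance")

  # alignment on common years only
  g <- gen_stock_recruit(a = 1, b = -0.001, temp_effect = 0.5, sigma = 0,
                         n_years = 30, seed = 2)
  an <- g$anomaly[6:30, ]
  cs <- correlate_survival_with_anomaly(g$stock, an)
  expect_equal(cs$n, 25)
  expect_error(correlate_survival_with_anomaly(g$stock, g$anomaly[1:2, ]),
               "overlapping")
})
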