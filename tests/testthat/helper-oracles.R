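# Independent oracles used across tests: closed-form and brute-force
# computations that never call the implementation paths they check.

# OLS by explicit normal equations
ols_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# percentile by linear interpolation between order statistics (type-7 rule),
# written out by hand
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Benjamini-Hochberg step-up rejection set by direct enumeration
bh_oracle_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k_star <- 0L
  for (k in seq_len(m)) if (ps[k] <= k * alpha / m) k_star <- k
  reject <- rep(FALSE, m)
  if (k_star > 0L) reject[ord[seq_len(k_star)]] <- TRUE
  reject
}

# first-order delta-method SD for the M_oto mixing model with independent
# uniform diet/DIC end members (variance width^2 / 12 each)
moto_delta_sd_oracle <- function(d13c_oto, diet_range, dic_range) {
  diet <- mean(diet_range)
  dic <- mean(dic_range)
  den <- diet - dic
  d_diet <- -(d13c_oto - dic) / den^2
  d_dic <- (d13c_oto - diet) / den^2
  v_diet <- diff(diet_range)^2 / 12
  v_dic <- diff(dic_range)^2 / 12
  sqrt(d_diet^2 * v_diet + d_dic^2 * v_dic)
}

# hand AIC under the profiled-variance Gaussian convention
aic_oracle <- function(y, X) {
  beta <- ols_oracle(X, y)
  rss <- sum((y - X %*% beta)^2)
  n <- length(y)
  n * log(rss / n) + 2 * (ncol(X) + 1)
}
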