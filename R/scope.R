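# Aerobic-scope envelope: the spread of the metabolic proxy M_oto across
# temperature bins proxies aerobic scope; the gap between the fitted upper
# (95th percentile, quadratic) and lower (5th percentile, Gaussian log-link)
# envelopes is maximal at the metabolically optimal temperature.

#' Bin (temperature, M_oto) pairs into 1 degC bins
#'
#' Bins are half-open intervals `[k, k+1)` anchored at integer degC with
#' centers at `k + 0.5`. Bins with fewer than `min_n` members are dropped to
#' avoid percentile estimates from under-sampled temperatures. Percentiles use
#' linear interpolation between order statistics.
#'
#' @param temps Temperatures (degC).
#' @param moto Matching M_oto values.
#' @param width Bin width in degC (default 1).
#' @param min_n Minimum members per retained bin (default 4).
#' @return data.frame of class `temp_bins` with columns `bin_lo`, `center`,
#'   `n`, `p95`, `p5`.
#' @export
bin_by_temperature <- function(temps, moto, width = 1, min_n = 4) {
  stopifnot(length(temps) == length(moto), width > 0)
  ok <- is.finite(temps) & is.finite(moto)
  temps <- temps[ok]; moto <- moto[ok]
  lo <- floor(temps / width) * width
  split_m <- split(moto, lo)
  n <- lengths(split_m)
  split_m <- split_m[n >= min_n]
  if (length(split_m) < 3L) {
    stop("fewer than 3 retained bins: envelope unfittable")
  }
  bin_lo <- as.numeric(names(split_m))
  res <- data.frame(
    bin_lo = bin_lo,
    center = bin_lo + width / 2,
    n = as.integer(lengths(split_m)),
    p95 = vapply(split_m, stats::quantile, numeric(1), probs = 0.95,
                 names = FALSE),
    p5 = vapply(split_m, stats::quantile, numeric(1), probs = 0.05,
                names = FALSE)
  )
  res <- res[order(res$center), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("temp_bins", "data.frame")
  res
}

#' Fit the upper M_oto envelope (quadratic on the 95th percentiles)
#'
#' Least-squares quadratic of the per-bin 95th-percentile M_oto against bin
#' center temperature, mirroring the parabolic temperature dependence of
#' maximum metabolic rate.
#'
#' @param bins A `temp_bins` data.frame (>= 3 bins).
#' @return Named numeric `(c0, c1, c2)` for `p95 ~ c0 + c1*T + c2*T^2`.
#' @export
fit_upper_envelope <- function(bins) {
  if (nrow(bins) < 3L) stop("need at least 3 bins for the quadratic fit")
  fit <- stats::lm(p95 ~ center + I(center^2), data = bins)
  co <- stats::coef(fit)
  c(c0 = unname(co[1L]), c1 = unname(co[2L]), c2 = unname(co[3L]))
}

#' Fit the lower M_oto envelope (Gaussian log-link on the 5th percentiles)
#'
#' Fits `E[p5] = exp(eta0 + eta1 * T)` by a Gaussian generalised linear model
#' with a log link (iteratively reweighted least squares), mirroring the
#' near-exponential temperature dependence of standard metabolic rate.
#'
#' @param bins A `temp_bins` data.frame with all `p5 > 0` (>= 2 bins).
#' @param tol Convergence tolerance on successive coefficient change.
#' @param maxit Maximum IRLS iterations.
#' @return Named numeric `(eta0, eta1)`.
#' @export
fit_lower_envelope <- function(bins, tol = 1e-8, maxit = 100) {
  if (nrow(bins) < 2L) stop("need at least 2 bins for the log-link fit")
  if (any(bins$p5 <= 0)) {
    stop("non-positive 5th-percentile M_oto in bin(s) at ",
         paste(bins$center[bins$p5 <= 0], collapse = ", "),
         " degC: inspect the data before fitting a log-link envelope")
  }
  start <- stats::coef(stats::lm(log(p5) ~ center, data = bins))
  fit <- stats::glm(p5 ~ center, data = bins,
                    family = stats::gaussian(link = "log"),
                    start = start,
                    control = stats::glm.control(epsilon = tol, maxit = maxit))
  if (!fit$converged) stop("log-link envelope fit did not converge")
  co <- stats::coef(fit)
  c(eta0 = unname(co[1L]), eta1 = unname(co[2L]))
}

#' Optimal temperature from the envelope gap
#'
#' Evaluates the gap `upper(T) - lower(T)` on a regular grid over the occupied
#' bin range; the grid argmax is the metabolically optimal temperature (the
#' temperature of widest aerobic scope). Ties are broken toward the lowest
#' temperature.
#'
#' @param upper Quadratic coefficients from [fit_upper_envelope()].
#' @param lower Log-link coefficients from [fit_lower_envelope()].
#' @param range Length-2 numeric, the occupied-bin temperature range.
#' @param grid_step Grid step in degC (default 0.1).
#' @return A list with `t_opt`, `gap` (data.frame `temp_c`, `gap`), and
#'   `all_nonpositive` (TRUE when the gap never exceeds 0, with a warning).
#' @export
optimal_temperature <- function(upper, lower, range, grid_step = 0.1) {
  stopifnot(length(range) == 2L, range[1] <= range[2], grid_step > 0)
  tt <- seq(range[1], range[2], by = grid_step)
  up <- upper[["c0"]] + upper[["c1"]] * tt + upper[["c2"]] * tt^2
  lw <- exp(lower[["eta0"]] + lower[["eta1"]] * tt)
  gap <- up - lw
  all_np <- all(gap <= 0)
  if (all_np) warning("envelope gap is nowhere positive")
  list(
    t_opt = tt[which.max(gap)],
    gap = data.frame(temp_c = tt, gap = gap),
    all_nonpositive = all_np
  )
}

#' Estimate the full aerobic-scope envelope for one data set
#'
#' Bins the (temperature, M_oto) pairs, fits both envelopes, and locates the
#' optimal temperature.
#'
#' @inheritParams bin_by_temperature
#' @param grid_step Gap-curve grid step (degC).
#' @return An object of class `scope_envelope` with elements `bins`, `upper`,
#'   `lower`, `gap`, `t_opt`, `range`.
#' @export
estimate_scope_envelope <- function(temps, moto, width = 1, min_n = 4,
                                    grid_step = 0.1) {
  bins <- bin_by_temperature(temps, moto, width, min_n)
  upper <- fit_upper_envelope(bins)
  lower <- fit_lower_envelope(bins)
  rng <- c(min(bins$bin_lo), max(bins$bin_lo) + width)
  opt <- optimal_temperature(upper, lower, rng, grid_step)
  structure(
    list(bins = bins, upper = upper, lower = lower,
         gap = opt$gap, t_opt = opt$t_opt, range = rng,
         all_nonpositive = opt$all_nonpositive),
    class = "scope_envelope"
  )
}

#' @export
print.scope_envelope <- function(x, ...) {
  cat("Aerobic-scope envelope over", nrow(x$bins), "temperature bins\n")
  cat(sprintf("  upper (p95): %.4g %+.4g*T %+.4g*T^2\n",
              x$upper[["c0"]], x$upper[["c1"]], x$upper[["c2"]]))
  cat(sprintf("  lower (p5):  exp(%.4g %+.4g*T)\n",
              x$lower[["eta0"]], x$lower[["eta1"]]))
  cat(sprintf("  optimal temperature: %.1f degC (range %.0f..%.0f)\n",
              x$t_opt, x$range[1], x$range[2]))
  invisible(x)
}
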