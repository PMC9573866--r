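# Stock-recruitment survival index (Ricker log residuals) and the supporting
# statistics: Pearson correlation with exact t-based p-values,
# Benjamini-Hochberg correction, and AIC selection of a quadratic temperature
# term for length-temperature relationships.

#' Fit a Ricker stock-recruitment model
#'
#' Linearised Ricker fit: OLS of `ln(R_t / S_t)` on `S_t`, giving
#' `R = S * exp(a + b * S)` coefficients.
#'
#' @param ssb Spawning stock biomass per year (positive).
#' @param recruits Recruitment per year-class (positive).
#' @return Named numeric `(a, b)`.
#' @export
fit_ricker <- function(ssb, recruits) {
  stopifnot(length(ssb) == length(recruits))
  if (length(ssb) < 3L) stop("need at least 3 years")
  if (any(ssb <= 0) || any(recruits <= 0)) {
    stop("spawning stock biomass and recruitment must be positive")
  }
  if (stats::var(ssb) == 0) stop("zero variance in spawning stock biomass")
  y <- log(recruits / ssb)
  fit <- stats::lm(y ~ ssb)
  c(a = unname(stats::coef(fit)[1L]), b = unname(stats::coef(fit)[2L]))
}

#' Log recruitment residuals (LNRR), an early-survival index
#'
#' `LNRR_t = ln(R_t / S_t) - (a + b * S_t)`: survival anomalies after
#' removing the density-dependent expectation of the Ricker model. When
#' `(a, b)` are the internal OLS fit the residuals sum to zero.
#'
#' @inheritParams fit_ricker
#' @param coef Optional named `(a, b)`; fitted internally when omitted.
#' @return Numeric vector of LNRR, one per year.
#' @export
lnrr <- function(ssb, recruits, coef = NULL) {
  if (is.null(coef)) coef <- fit_ricker(ssb, recruits)
  log(recruits / ssb) - (coef[["a"]] + coef[["b"]] * ssb)
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample correlation with the exact two-sided p-value from the t transform
#' `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite).
#' @return A list with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  # relative threshold: residual float noise (e.g. LNRR of an exact Ricker
  # series) is degenerate, not signal
  degen <- function(v) stats::sd(v) <= 1e-10 * max(1, abs(mean(v)))
  if (degen(x) || degen(y)) {
    stop("zero variance in x or y: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up procedure: with p-values sorted ascending, reject hypotheses
#' `1..k*` where `k*` is the largest `k` with `p_(k) <= k * alpha / m`;
#' adjusted p-values by the monotone step-up transform.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return A list with `adjusted` (same order as input), `reject` (logical,
#'   same order) and `alpha`.
#' @export
bh_adjust <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = adj <= alpha, alpha = alpha)
}

#' AIC selection of a quadratic temperature term
#'
#' Fits null (intercept), linear (`~ T`) and quadratic (`~ T + T^2`) OLS
#' models of length on temperature and picks the minimum-AIC model, with AIC
#' computed as `n * ln(RSS / n) + 2 * (k + 1)` (Gaussian likelihood with
#' profiled variance; `k` coefficients including the intercept). Ties are
#' broken toward fewer parameters.
#'
#' @param lengths Response (e.g. back-calculated standard length, mm).
#' @param temps Mean experienced temperature (degC).
#' @return A list of class `regression_choice`: `chosen` (`"null"`,
#'   `"linear"`, `"quadratic"`), `aic` (named vector), `fits` (lm objects),
#'   `coef` and `p_values` of the chosen model.
#' @export
quadratic_term_selection <- function(lengths, temps) {
  stopifnot(length(lengths) == length(temps))
  ok <- is.finite(lengths) & is.finite(temps)
  lengths <- lengths[ok]; temps <- temps[ok]
  if (length(lengths) < 5L) stop("need at least 5 observations")
  if (stats::var(temps) == 0) stop("degenerate design: all temperatures equal")
  fits <- list(
    null = stats::lm(lengths ~ 1),
    linear = stats::lm(lengths ~ temps),
    quadratic = stats::lm(lengths ~ temps + I(temps^2))
  )
  n <- length(lengths)
  # floor RSS at machine-level noise so exact fits tie (instead of comparing
  # logs of float residue) and the parsimony tie-break applies
  rss_floor <- 1e-10 * max(sum(lengths^2), .Machine$double.eps)
  aic <- vapply(fits, function(f) {
    rss <- max(sum(stats::resid(f)^2), rss_floor)
    k <- length(stats::coef(f))
    n * log(rss / n) + 2 * (k + 1)
  }, numeric(1))
  # ties toward fewer parameters: candidates ordered null < linear < quadratic
  chosen <- names(aic)[which(aic <= min(aic) + 1e-9)][1L]
  s <- suppressWarnings(summary(fits[[chosen]]))
  structure(
    list(chosen = chosen, aic = aic, fits = fits,
         coef = stats::coef(fits[[chosen]]),
         p_values = s$coefficients[, "Pr(>|t|)"]),
    class = "regression_choice"
  )
}

#' @export
print.regression_choice <- function(x, ...) {
  cat("Temperature-length model selection (AIC):\n")
  for (m in names(x$aic)) {
    cat(sprintf("  %-10s AIC = %.3f%s\n", m, x$aic[[m]],
                if (m == x$chosen) "  <- chosen" else ""))
  }
  invisible(x)
}

#' Correlate the Ricker survival index with a temperature anomaly series
#'
#' Aligns the stock-recruit series and the anomaly series on common years,
#' computes LNRR internally from the overlapping years, and returns the
#' Pearson correlation with its two-sided p-value.
#'
#' @param stock data.frame with columns `year`, `ssb`, `recruits`.
#' @param anomaly data.frame with columns `year`, `anomaly`.
#' @return A list with `r`, `p`, `n` and the per-year `lnrr` used.
#' @export
correlate_survival_with_anomaly <- function(stock, anomaly) {
  stopifnot(all(c("year", "ssb", "recruits") %in% names(stock)),
            all(c("year", "anomaly") %in% names(anomaly)))
  years <- intersect(stock$year, anomaly$year)
  if (length(years) < 3L) stop("fewer than 3 overlapping years")
  s <- stock[match(years, stock$year), ]
  x <- anomaly$anomaly[match(years, anomaly$year)]
  res <- lnrr(s$ssb, s$recruits)
  ct <- pearson_with_p(res, x)
  c(ct, list(lnrr = data.frame(year = years, lnrr = res)))
}
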