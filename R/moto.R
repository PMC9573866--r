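# Carbon-isotope mixing model for the proportion of metabolically derived
# carbon in otolith carbonate (M_oto), a field-metabolic-rate proxy, with
# Monte Carlo propagation of diet and DIC end-member uncertainty.

#' Isotope context for the M_oto mixing model
#'
#' Region-specific d13C end-member ranges: the diet (metabolic carbon) range
#' derived from sardine muscle and zooplankton d13C, and the dissolved
#' inorganic carbon (DIC) range from era-matched seawater observations
#' (era-specific because of the oceanic Suess effect). JP: diet -22.0..-19.0,
#' DIC +0.53..+1.05 permil; CA: diet -21.5..-18.5, DIC -0.31..+2.20 permil.
#' The net fractionation term epsilon defaults to 0.
#'
#' @param region `"JP"` or `"CA"`, or `NULL` to pass explicit ranges.
#' @param d13c_diet_range,d13c_dic_range Length-2 numeric (permil VPDB).
#' @param epsilon Net isotopic fractionation (permil), default 0.
#' @return An object of class `isotope_context`.
#' @export
isotope_context <- function(region = NULL, d13c_diet_range = NULL,
                            d13c_dic_range = NULL, epsilon = 0) {
  if (!is.null(region)) {
    preset <- region_preset(region)
    if (is.null(d13c_diet_range)) d13c_diet_range <- preset$d13c_diet_range
    if (is.null(d13c_dic_range)) d13c_dic_range <- preset$d13c_dic_range
  }
  stopifnot(length(d13c_diet_range) == 2L, length(d13c_dic_range) == 2L,
            d13c_diet_range[1] <= d13c_diet_range[2],
            d13c_dic_range[1] <= d13c_dic_range[2])
  if (d13c_diet_range[2] >= d13c_dic_range[1]) {
    stop("diet d13C range must lie entirely below the DIC range")
  }
  structure(
    list(region = if (is.null(region)) NA_character_ else region,
         d13c_diet_range = d13c_diet_range,
         d13c_dic_range = d13c_dic_range,
         epsilon = epsilon),
    class = "isotope_context"
  )
}

#' @export
print.isotope_context <- function(x, ...) {
  cat("Isotope context", if (!is.na(x$region)) paste0("(", x$region, ")"), "\n")
  cat(sprintf("  d13C diet: %.2f..%.2f permil; d13C DIC: %.2f..%.2f permil; epsilon = %g\n",
              x$d13c_diet_range[1], x$d13c_diet_range[2],
              x$d13c_dic_range[1], x$d13c_dic_range[2], x$epsilon))
  invisible(x)
}

#' Point estimate of M_oto from otolith d13C
#'
#' Two-end-member mixing: otolith carbonate carbon is a mixture of seawater
#' DIC and metabolically derived (diet) carbon, so
#' `M_oto = (d13C_oto - d13C_DIC) / (d13C_diet - d13C_DIC) + epsilon`.
#' Values are not clamped to \[0, 1\]: under measurement noise the mixing
#' model can produce values slightly outside and these are informative.
#'
#' @param d13c_oto Otolith d13C (permil VPDB), vectorised.
#' @param d13c_dic Seawater DIC d13C (permil VPDB).
#' @param d13c_diet Diet d13C (permil VPDB).
#' @param epsilon Net fractionation (permil), default 0.
#' @return M_oto (unitless).
#' @export
estimate_moto <- function(d13c_oto, d13c_dic, d13c_diet, epsilon = 0) {
  if (any(abs(d13c_diet - d13c_dic) < .Machine$double.eps)) {
    stop("d13c_diet equals d13c_dic: zero denominator in the mixing model")
  }
  (d13c_oto - d13c_dic) / (d13c_diet - d13c_dic) + epsilon
}

#' Monte Carlo M_oto with end-member uncertainty
#'
#' Draws the diet and DIC d13C end members independently and uniformly over
#' their context ranges and returns the mean and SD of the resulting M_oto
#' values.
#'
#' @param d13c_oto Otolith d13C (permil VPDB), scalar or vector (each value
#'   gets its own summary over the same draws).
#' @param context An [isotope_context()].
#' @param n_draws Number of draws (>= 100; default 10000).
#' @param seed Integer seed.
#' @return data.frame with columns `d13c_oto`, `moto_mean`, `moto_sd`,
#'   `n_draws`.
#' @export
mc_moto <- function(d13c_oto, context, n_draws = 10000, seed = 1) {
  stopifnot(inherits(context, "isotope_context"))
  if (n_draws < 100) stop("n_draws must be at least 100")
  set.seed(seed)
  diet <- stats::runif(n_draws, context$d13c_diet_range[1],
                       context$d13c_diet_range[2])
  dic <- stats::runif(n_draws, context$d13c_dic_range[1],
                      context$d13c_dic_range[2])
  out <- vapply(d13c_oto, function(d) {
    m <- estimate_moto(d, dic, diet, context$epsilon)
    c(mean(m), stats::sd(m))
  }, numeric(2))
  data.frame(d13c_oto = d13c_oto, moto_mean = out[1, ], moto_sd = out[2, ],
             n_draws = n_draws)
}

#' Stage-averaged M_oto with Tukey outlier exclusion
#'
#' Maps each milled interval to the life stage containing its midpoint age,
#' averages M_oto per fish within each stage, then flags values outside the
#' Tukey fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (quartiles by linear
#' interpolation, computed across fish within each stage) as outliers.
#' Stages with fewer than 4 fish get no exclusion (with a warning). Intervals
#' whose midpoint falls beyond the last stage window are dropped.
#'
#' @param estimates data.frame with columns `fish_id`, `interval_start_dph`,
#'   `interval_end_dph`, `moto`.
#' @param region `"JP"` or `"CA"` (defines the stage windows).
#' @return A list with `stage_means` (data.frame `fish_id`, `stage`, `moto`,
#'   `outlier`), `retained` (the non-outlier subset) and `exclusions`
#'   (log of dropped/flagged rows).
#' @export
stage_average_moto <- function(estimates, region = c("JP", "CA")) {
  stopifnot(all(c("fish_id", "interval_start_dph", "interval_end_dph", "moto")
                %in% names(estimates)))
  region <- match.arg(region)
  mid <- floor((estimates$interval_start_dph + estimates$interval_end_dph) / 2)
  stage <- assign_stage(mid, region)
  dropped <- estimates[is.na(stage), , drop = FALSE]
  keep <- !is.na(stage)
  est <- estimates[keep, , drop = FALSE]
  stage <- stage[keep]
  agg <- stats::aggregate(
    list(moto = est$moto),
    by = list(fish_id = est$fish_id, stage = stage), FUN = mean)
  agg$outlier <- FALSE
  exclusions <- list()
  if (nrow(dropped)) {
    exclusions[[length(exclusions) + 1L]] <- data.frame(
      fish_id = dropped$fish_id, stage = NA_character_,
      moto = dropped$moto, reason = "interval beyond last stage window",
      stringsAsFactors = FALSE)
  }
  for (s in unique(agg$stage)) {
    idx <- which(agg$stage == s)
    if (length(idx) < 4L) {
      warning(sprintf(
        "stage %s has %d fish (< 4); no outlier exclusion applied",
        s, length(idx)))
      next
    }
    v <- agg$moto[idx]
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    out <- v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr
    agg$outlier[idx[out]] <- TRUE
    if (any(out)) {
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        fish_id = agg$fish_id[idx[out]], stage = s, moto = v[out],
        reason = "outside Tukey 1.5*IQR fences", stringsAsFactors = FALSE)
    }
  }
  list(
    stage_means = agg,
    retained = agg[!agg$outlier, , drop = FALSE],
    exclusions = if (length(exclusions)) do.call(rbind, exclusions) else
      data.frame(fish_id = character(), stage = character(),
                 moto = numeric(), reason = character(),
                 stringsAsFactors = FALSE)
  )
}
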