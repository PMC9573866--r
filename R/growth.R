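# Otolith radius accumulation and biological-intercept back-calculation of
# standard length, with Monte Carlo propagation of the initial-size assumption.

#' Cumulative otolith radius from daily increment widths
#'
#' The otolith radius at each age is the radius at first increment deposition
#' plus the sum of all daily increment widths up to that age.
#'
#' @param widths Numeric vector of daily increment widths (um), one per day
#'   starting at `first_increment_dph`; all positive.
#' @param or_first Otolith radius (um) at the age of first increment
#'   deposition.
#' @param first_increment_dph Age (dph) of the first increment.
#' @return data.frame with columns `dph` and `or_um`; the first row is
#'   (`first_increment_dph`, `or_first`), so `length(widths) + 1` rows.
#' @export
cumulate_radius <- function(widths, or_first, first_increment_dph = 3) {
  if (anyNA(widths)) {
    stop("missing increment widths at day offset(s): ",
         paste(which(is.na(widths)), collapse = ", "))
  }
  stopifnot(all(widths > 0), or_first >= 0)
  data.frame(
    dph = first_increment_dph + seq.int(0L, length(widths)),
    or_um = or_first + cumsum(c(0, widths))
  )
}

#' Biological-intercept back-calculation of standard length
#'
#' Assumes a linear otolith-radius/standard-length relation anchored at the
#' size at first increment deposition:
#' `SL_n = (SL_catch - SL_first) * (OR_n - OR_first) / (OR_catch - OR_first)
#'  + SL_first`.
#'
#' @param or_n Otolith radii (um) at the ages of interest.
#' @param sl_catch Standard length at catch (mm).
#' @param or_catch Otolith radius at catch (um).
#' @param sl_first Standard length (mm) at first increment deposition
#'   (defaults: 5.9 mm JP, 5.5 mm CA; see [region_preset()]).
#' @param or_first Otolith radius (um) at first increment deposition.
#' @return Back-calculated standard lengths (mm), same length as `or_n`.
#' @export
back_calculate_sl <- function(or_n, sl_catch, or_catch, sl_first, or_first) {
  if (or_catch <= or_first) {
    stop("or_catch must exceed or_first (degenerate denominator)")
  }
  if (sl_catch <= sl_first) stop("sl_catch must exceed sl_first")
  (sl_catch - sl_first) * (or_n - or_first) / (or_catch - or_first) + sl_first
}

#' Monte Carlo uncertainty of back-calculated length from the initial size
#'
#' The size at first increment deposition is only known to lie in a range
#' (3.8-6.5 mm from rearing experiments); initial lengths are drawn uniformly
#' over that range and the SD of the back-calculated length at each age is
#' reported. Because `SL_n` is affine in `SL_first`, the SD shrinks linearly
#' to exactly 0 at the age of catch, which is reported analytically.
#'
#' @inheritParams back_calculate_sl
#' @param sl_first_range Length-2 numeric, low < high (mm).
#' @param n_draws Number of Monte Carlo draws (>= 100; default 10000).
#' @param seed Integer seed for reproducibility.
#' @return data.frame with columns `or_um`, `sl_sd_mm`.
#' @export
mc_backcalc_uncertainty <- function(or_n, sl_catch, or_catch, or_first,
                                    sl_first_range = c(3.8, 6.5),
                                    n_draws = 10000, seed = 1) {
  stopifnot(length(sl_first_range) == 2L,
            sl_first_range[1] <= sl_first_range[2])
  if (n_draws < 100) stop("n_draws must be at least 100")
  if (or_catch <= or_first) stop("or_catch must exceed or_first")
  set.seed(seed)
  draws <- stats::runif(n_draws, sl_first_range[1], sl_first_range[2])
  # SL_n = sl_first * (1 - w) + sl_catch * w with w = (OR_n-OR_first)/(OR_catch-OR_first)
  w <- (or_n - or_first) / (or_catch - or_first)
  sd_first <- stats::sd(draws)
  sl_sd <- abs(1 - w) * sd_first
  sl_sd[abs(or_n - or_catch) < .Machine$double.eps^0.5 * max(1, or_catch)] <- 0
  data.frame(or_um = or_n, sl_sd_mm = sl_sd)
}

#' Full back-calculation for one otolith profile
#'
#' Convenience wrapper combining [cumulate_radius()], [back_calculate_sl()]
#' and [mc_backcalc_uncertainty()] for one fish.
#'
#' @param widths Daily increment widths (um).
#' @param sl_catch Standard length at catch (mm).
#' @param or_first Radius at first increment (um).
#' @param region `"JP"` or `"CA"`; supplies `sl_first` and the first-increment
#'   age.
#' @param or_catch Radius at catch (um); defaults to the accumulated radius.
#' @param n_draws,seed Monte Carlo settings for the uncertainty column.
#' @return data.frame with `dph`, `or_um`, `sl_mm`, `sl_sd_mm`.
#' @export
backcalc_profile <- function(widths, sl_catch, or_first,
                             region = c("JP", "CA"), or_catch = NULL,
                             n_draws = 10000, seed = 1) {
  preset <- region_preset(region)
  radii <- cumulate_radius(widths, or_first, preset$first_increment_dph)
  if (is.null(or_catch)) or_catch <- radii$or_um[nrow(radii)]
  if (or_catch < radii$or_um[nrow(radii)] - 1e-9) {
    stop("or_catch smaller than accumulated radius")
  }
  sl <- back_calculate_sl(radii$or_um, sl_catch, or_catch,
                          preset$sl_first_mm, or_first)
  mc <- mc_backcalc_uncertainty(radii$or_um, sl_catch, or_catch, or_first,
                                preset$sl_first_range_mm, n_draws, seed)
  data.frame(dph = radii$dph, or_um = radii$or_um, sl_mm = sl,
             sl_sd_mm = mc$sl_sd_mm)
}

#' Per-bin medians of growth against temperature with a running mean
#'
#' Groups growth values into 1 degC temperature bins anchored at integers,
#' takes the median per occupied bin, and smooths the bin medians with a
#' 3-window running mean (shorter window at the edges).
#'
#' @param values Growth values (e.g. increment width um/day or somatic growth
#'   mm/day), one per interval.
#' @param temps Matching temperatures (degC).
#' @param bin_width Bin width in degC (default 1).
#' @return data.frame with `bin_center`, `n`, `median`, `running_mean`,
#'   ordered by bin.
#' @export
median_growth_by_temp_bin <- function(values, temps, bin_width = 1) {
  stopifnot(length(values) == length(temps), bin_width > 0)
  ok <- is.finite(values) & is.finite(temps)
  values <- values[ok]; temps <- temps[ok]
  if (length(values) == 0L) stop("no finite (value, temperature) pairs")
  lo <- floor(temps / bin_width) * bin_width
  med <- tapply(values, lo, stats::median)
  centers <- as.numeric(names(med)) + bin_width / 2
  ord <- order(centers)
  med <- as.numeric(med)[ord]; centers <- centers[ord]
  n <- as.integer(table(lo))[ord]
  k <- length(med)
  run <- vapply(seq_len(k), function(i) {
    mean(med[max(1, i - 1):min(k, i + 1)])
  }, numeric(1))
  data.frame(bin_center = centers, n = n, median = med, running_mean = run)
}
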