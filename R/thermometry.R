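# Oxygen-isotope thermometry: seawater d18O-salinity calibrations, the
# aragonite otolith fractionation line, and monthly quadratic thermometers
# built from hydrographic temperature/salinity observations.

# Otolith d18O responds to temperature with slope -0.18 permil/degC and
# intercept +2.69 permil relative to seawater d18O (sardine aragonite line).
.OTO_T_SLOPE <- -0.18
.OTO_T_INTERCEPT <- 2.69

#' Acid-fractionation adjustment between analytical lines
#'
#' Otolith powders reacted with phosphoric acid at 72 degC on the automated
#' line carry a temperature-dependent acid-fractionation offset relative to
#' the 25 degC micro-volume line; 0.09 permil is subtracted from values from
#' the 72 degC instrument so both lines are on a common scale.
#'
#' @param d18o Numeric vector, otolith d18O (permil VPDB).
#' @param instrument Character vector, one of `"micro25C"` or `"auto72C"` per
#'   value (recycled if length 1).
#' @return Adjusted d18O values (permil VPDB).
#' @export
acid_fractionation_adjust <- function(d18o, instrument) {
  if (length(instrument) == 1L) instrument <- rep(instrument, length(d18o))
  stopifnot(length(instrument) == length(d18o))
  bad <- !instrument %in% c("micro25C", "auto72C")
  if (any(bad)) {
    stop("unknown instrument tag(s): ",
         paste(unique(instrument[bad]), collapse = ", "))
  }
  d18o - 0.09 * (instrument == "auto72C")
}

new_sw_calibration <- function(slope, intercept, provenance,
                               n = NA_integer_, r_squared = NA_real_,
                               residual_sd = NA_real_) {
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(
    list(slope = slope, intercept = intercept, provenance = provenance,
         n = n, r_squared = r_squared, residual_sd = residual_sd),
    class = "sw_calibration"
  )
}

#' Fixed seawater d18O-salinity calibrations
#'
#' `"fixed-KO"` is the Kuroshio-Oyashio line (slope 0.56, intercept -19.06);
#' `"fixed-CA"` is the California Current line fitted to CalCOFI seawater
#' samples (slope 0.279, intercept -9.63).
#'
#' @param which `"fixed-KO"` or `"fixed-CA"`.
#' @return An object of class `sw_calibration`.
#' @export
sw_calibration_fixed <- function(which = c("fixed-KO", "fixed-CA")) {
  which <- match.arg(which)
  if (which == "fixed-KO") {
    new_sw_calibration(0.56, -19.06, "fixed-KO")
  } else {
    new_sw_calibration(0.279, -9.63, "fixed-CA")
  }
}

#' @export
print.sw_calibration <- function(x, ...) {
  cat(sprintf("Seawater d18O calibration (%s): d18O = %.4g * S %+.4g\n",
              x$provenance, x$slope, x$intercept))
  if (!is.na(x$n)) {
    cat(sprintf("  fitted on n = %d, r^2 = %.3f, residual SD = %.3g permil\n",
                x$n, x$r_squared, x$residual_sd))
  }
  invisible(x)
}

#' Fit a seawater d18O-salinity regression
#'
#' Ordinary least squares of seawater d18O (permil VSMOW) on salinity.
#'
#' @param salinity Numeric vector (practical salinity).
#' @param d18o_sw Numeric vector, seawater d18O (permil VSMOW).
#' @return An object of class `sw_calibration` with fit diagnostics.
#' @export
fit_sw_salinity_regression <- function(salinity, d18o_sw) {
  stopifnot(length(salinity) == length(d18o_sw))
  ok <- is.finite(salinity) & is.finite(d18o_sw)
  salinity <- salinity[ok]; d18o_sw <- d18o_sw[ok]
  if (length(unique(salinity)) < 2L) {
    stop("degenerate salinity variance: need at least 2 distinct salinities")
  }
  if (length(salinity) < 3L) stop("need at least 3 observations")
  fit <- stats::lm(d18o_sw ~ salinity)
  s <- summary(fit)
  new_sw_calibration(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    provenance = "fitted",
    n = length(salinity),
    r_squared = s$r.squared,
    residual_sd = s$sigma
  )
}

#' Predict seawater d18O from salinity
#'
#' @param salinity Numeric vector (practical salinity).
#' @param calib A `sw_calibration` object.
#' @return Seawater d18O (permil VSMOW).
#' @export
sw_d18o_from_salinity <- function(salinity, calib) {
  stopifnot(inherits(calib, "sw_calibration"))
  calib$slope * salinity + calib$intercept
}

#' Forward otolith d18O model
#'
#' Predicted otolith d18O for a given seawater d18O and temperature:
#' `d18O_oto = d18O_sw - 0.18 * T + 2.69`.
#'
#' @param d18o_sw Seawater d18O (permil VSMOW).
#' @param temp_c Temperature (degC).
#' @return Otolith d18O (permil VPDB).
#' @export
forward_otolith_d18o <- function(d18o_sw, temp_c) {
  d18o_sw + .OTO_T_SLOPE * temp_c + .OTO_T_INTERCEPT
}

#' Invert otolith d18O to temperature at fixed seawater d18O
#'
#' Exact algebraic inverse of [forward_otolith_d18o()]; the default seawater
#' value of -0.32 permil is the observed mean in the Southern California Bight,
#' where horizontal and vertical variation is small.
#'
#' @param d18o_oto Otolith d18O (permil VPDB).
#' @param d18o_sw Seawater d18O (permil VSMOW); default -0.32.
#' @return Temperature (degC).
#' @export
invert_fixed_sw <- function(d18o_oto, d18o_sw = -0.32) {
  (d18o_sw + .OTO_T_INTERCEPT - d18o_oto) / (-.OTO_T_SLOPE)
}

#' Temperature error induced by a seawater d18O offset
#'
#' A seawater-d18O offset of `delta` permil maps to a temperature offset of
#' `delta / 0.18` degC under the otolith fractionation slope; the observed
#' +/-0.12 permil seasonal/inter-annual range off Southern California thus
#' bounds the thermometry error below 0.7 degC.
#'
#' @param delta_d18o_sw Non-negative seawater d18O offset (permil).
#' @return Temperature error (degC).
#' @export
sw_variation_to_temp_error <- function(delta_d18o_sw) {
  stopifnot(all(delta_d18o_sw >= 0))
  delta_d18o_sw / (-.OTO_T_SLOPE)
}

#' Build a monthly quadratic thermometer from hydrographic observations
#'
#' For each surface temperature/salinity observation of one calendar month the
#' implied otolith d18O is computed through the seawater d18O-salinity
#' calibration and the forward fractionation line; temperature is then fitted
#' against that d18O by least-squares quadratic, `T = a*d^2 + b*d + c`. The
#' root-mean-square error over the fitting set is a proxy for thermometry
#' accuracy, and the observed d18O range is recorded as the validity range.
#' With fewer than 3 distinct implied d18O values, or an ill-conditioned
#' quadratic design, the fit falls back to a linear law (a = 0) with a message.
#'
#' @param obs data.frame with columns `temp_c` and `salinity` (one month's
#'   surface observations); a `month` column, if present, must be constant.
#' @param sw_calib A `sw_calibration` object.
#' @param month Calendar month 1-12 the thermometer is keyed by (taken from
#'   `obs$month` when omitted).
#' @return An object of class `monthly_thermometer` with elements `month`,
#'   `coef` (a, b, c), `rmse`, `d18o_range`, `n_obs`, `degenerate`.
#' @export
build_monthly_thermometer <- function(obs, sw_calib, month = NULL) {
  stopifnot(is.data.frame(obs), all(c("temp_c", "salinity") %in% names(obs)))
  if (is.null(month)) {
    if (!"month" %in% names(obs)) stop("month not given and absent from obs")
    month <- unique(obs$month)
    if (length(month) != 1L) stop("observations span several months")
  }
  if (!(month %in% 1:12)) stop("month must be in 1..12")
  d <- forward_otolith_d18o(sw_d18o_from_salinity(obs$salinity, sw_calib),
                            obs$temp_c)
  temp <- obs$temp_c
  if (length(d) < 3L || length(unique(round(d, 12))) < 3L) {
    stop("need at least 3 observations with distinct implied d18O")
  }
  fit <- stats::lm(temp ~ I(d^2) + d)
  degenerate <- anyNA(stats::coef(fit)) ||
    kappa(stats::model.matrix(fit), exact = TRUE) > 1e10
  if (degenerate) {
    message("quadratic thermometer ill-conditioned for month ", month,
            "; falling back to linear fit")
    fit <- stats::lm(temp ~ d)
    co <- c(a = 0, b = unname(stats::coef(fit)[2L]),
            c = unname(stats::coef(fit)[1L]))
  } else {
    co <- c(a = unname(stats::coef(fit)[2L]),
            b = unname(stats::coef(fit)[3L]),
            c = unname(stats::coef(fit)[1L]))
  }
  structure(
    list(month = as.integer(month), coef = co,
         rmse = sqrt(mean(stats::resid(fit)^2)),
         d18o_range = range(d), n_obs = length(d),
         degenerate = degenerate),
    class = "monthly_thermometer"
  )
}

#' @export
print.monthly_thermometer <- function(x, ...) {
  cat(sprintf(
    "Monthly thermometer (month %d, n = %d): T = %.4g*d^2 %+.4g*d %+.4g\n",
    x$month, x$n_obs, x$coef["a"], x$coef["b"], x$coef["c"]))
  cat(sprintf("  RMSE %.3g degC; valid d18O %.3g..%.3g permil\n",
              x$rmse, x$d18o_range[1], x$d18o_range[2]))
  invisible(x)
}

#' Estimate temperature from otolith d18O with a monthly thermometer
#'
#' Evaluates the fitted quadratic `T(d18O)`. Values beyond the thermometer's
#' validity range are tolerated up to an extrapolation margin of 0.5 permil
#' (with a warning); beyond that the quadratic is unconstrained and an error
#' is raised.
#'
#' @param d18o_oto Otolith d18O (permil VPDB), scalar or vector.
#' @param thermometer A `monthly_thermometer`.
#' @param margin Extrapolation margin (permil) beyond the validity range.
#' @return Temperature (degC).
#' @export
invert_quadratic <- function(d18o_oto, thermometer, margin = 0.5) {
  stopifnot(inherits(thermometer, "monthly_thermometer"))
  rng <- thermometer$d18o_range
  too_far <- d18o_oto < rng[1] - margin | d18o_oto > rng[2] + margin
  if (any(too_far)) {
    stop(sprintf(
      "otolith d18O %.3g permil beyond validity range [%.3g, %.3g] + %.2g margin",
      d18o_oto[too_far][1], rng[1], rng[2], margin))
  }
  outside <- d18o_oto < rng[1] | d18o_oto > rng[2]
  if (any(outside)) {
    warning(sprintf(
      "%d otolith d18O value(s) outside validity range [%.3g, %.3g]; extrapolating",
      sum(outside), rng[1], rng[2]))
  }
  co <- thermometer$coef
  unname(co["a"] * d18o_oto^2 + co["b"] * d18o_oto + co["c"])
}

#' Calendar month of a milled interval's median date
#'
#' Each milled otolith area is assigned the thermometer of the month in which
#' its median deposition date falls: `hatch_date + floor((start + end) / 2)`
#' days.
#'
#' @param hatch_date A `Date` (or string coercible to one).
#' @param interval Numeric length-2 vector `(start_dph, end_dph)`.
#' @return Integer month 1-12.
#' @export
assign_interval_month <- function(hatch_date, interval) {
  hatch_date <- as.Date(hatch_date)
  stopifnot(!is.na(hatch_date), length(interval) == 2L,
            interval[1] <= interval[2])
  mid <- hatch_date + floor((interval[1] + interval[2]) / 2)
  as.integer(format(mid, "%m"))
}

#' Per-interval thermal history of one fish
#'
#' Converts each milled interval's (acid-adjusted) otolith d18O to temperature,
#' either by fixed-seawater inversion (CA mode) or with the monthly quadratic
#' thermometer matching the interval's median date (JP mode).
#'
#' @param isotopes data.frame with columns `interval_start_dph`,
#'   `interval_end_dph`, `d18o_vpdb` and optionally `instrument`.
#' @param mode `"fixed"` or `"monthly"`.
#' @param hatch_date Required in monthly mode.
#' @param thermometers In monthly mode, a list of `monthly_thermometer`
#'   objects indexed by month (e.g. `thermometers[[4]]` for April).
#' @param d18o_sw Fixed seawater d18O for fixed mode.
#' @param adjust_acid Apply [acid_fractionation_adjust()] using the
#'   `instrument` column before conversion (default TRUE when present).
#' @return data.frame with per-interval `temp_c`, `method`, `month`.
#' @export
thermal_history <- function(isotopes, mode = c("fixed", "monthly"),
                            hatch_date = NULL, thermometers = NULL,
                            d18o_sw = -0.32,
                            adjust_acid = "instrument" %in% names(isotopes)) {
  mode <- match.arg(mode)
  stopifnot(all(c("interval_start_dph", "interval_end_dph", "d18o_vpdb")
                %in% names(isotopes)))
  d <- isotopes$d18o_vpdb
  if (isTRUE(adjust_acid)) {
    d <- acid_fractionation_adjust(d, isotopes$instrument)
  }
  n <- nrow(isotopes)
  month <- rep(NA_integer_, n)
  if (mode == "fixed") {
    temp <- invert_fixed_sw(d, d18o_sw)
    method <- "fixed-sw"
  } else {
    if (is.null(hatch_date) || is.null(thermometers)) {
      stop("monthly mode needs hatch_date and thermometers")
    }
    temp <- numeric(n)
    for (i in seq_len(n)) {
      month[i] <- assign_interval_month(
        hatch_date, c(isotopes$interval_start_dph[i],
                      isotopes$interval_end_dph[i]))
      th <- thermometers[[month[i]]]
      if (is.null(th)) stop("no thermometer for month ", month[i])
      temp[i] <- invert_quadratic(d[i], th)
    }
    method <- "monthly-quadratic"
  }
  data.frame(
    interval_start_dph = isotopes$interval_start_dph,
    interval_end_dph = isotopes$interval_end_dph,
    temp_c = temp, method = method, month = month,
    stringsAsFactors = FALSE
  )
}
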