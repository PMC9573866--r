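# Synthetic-data generator with known ground truth. Every downstream stage
# (back-calculation, M_oto, thermometry, envelope, LNRR) has a forward model
# here run in the generative direction, so parameter-recovery tests need no
# external data.

.counter_seed <- function(seed, index) {
  # counter-based sub-stream: stable under changes of n_fish
  as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483647)
}

#' Parameters for a synthetic otolith cohort
#'
#' Defaults describe a plausible North Pacific cohort: stage mean temperatures
#' declining from 17 to 15 degC (JP; the observed northward drift toward the
#' Oyashio) or steady near 15 degC (CA), daily AR(1) temperature noise, a
#' dome-shaped true upper M_oto bound peaking near 16 degC with an exponential
#' true lower bound, growth proportional to the scope used, and isotope
#' measurement noise at the stated analytical precisions.
#'
#' @param region_preset `"JP"` or `"CA"`.
#' @param n_fish Number of fish (>= 1).
#' @param hatch_month Calendar month of hatching (1-12); fish hatch on the
#'   15th of that month.
#' @param hatch_year Calendar year of hatching.
#' @param stage_mean_temps Mean temperature (degC) per life stage (larval,
#'   early juvenile, late juvenile); days beyond the last stage keep the last
#'   mean.
#' @param ar1_phi,ar1_sigma AR(1) parameters of the daily temperature
#'   deviations (phi in \[0, 1), sigma in degC).
#' @param envelope_true List with `upper = c(c0, c1, c2)` (quadratic in T) and
#'   `lower = c(eta0, eta1)` (`exp(eta0 + eta1 * T)`), the true M_oto bounds.
#' @param base_increment_um Baseline daily increment width (um).
#' @param growth_gain_um Increment-width gain (um) per unit of scope used,
#'   i.e. per unit of `M_true - lower(T)`.
#' @param sl_per_or Somatic-growth slope (mm standard length per um otolith
#'   radius) used to set the catch length.
#' @param or_first_um Otolith radius at first increment deposition (um).
#' @param iso_noise_d18o,iso_noise_d13c Gaussian measurement noise SDs
#'   (permil) at the analytical precisions of the isotope lines.
#' @param jp_salinity Salinity used with the Kuroshio-Oyashio seawater line
#'   for the JP seawater d18O.
#' @param seed Integer seed; all per-fish streams derive from it by
#'   counter-based splitting, so increasing `n_fish` does not reshuffle
#'   earlier fish.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(region_preset = c("JP", "CA"),
                          n_fish = 100,
                          hatch_month = 4,
                          hatch_year = 2008,
                          stage_mean_temps = NULL,
                          ar1_phi = 0.6,
                          ar1_sigma = 1.2,
                          envelope_true = list(
                            # upper: 0.55 - 0.01*(T - 16)^2, a dome peaking at
                            # 16 degC; lower: Q10 = 2 exponential
                            upper = c(c0 = 0.55 - 0.01 * 16^2,
                                      c1 = 0.01 * 32, c2 = -0.01),
                            lower = c(eta0 = -3.23, eta1 = log(2) / 10)
                          ),
                          base_increment_um = 2,
                          growth_gain_um = 8,
                          sl_per_or = 0.25,
                          or_first_um = 10,
                          iso_noise_d18o = 0.10,
                          iso_noise_d13c = 0.15,
                          jp_salinity = 34.0,
                          seed = 1) {
  region_preset <- match.arg(region_preset)
  if (is.null(stage_mean_temps)) {
    stage_mean_temps <- if (region_preset == "JP") c(17, 16, 15)
                        else c(15.5, 15, 15)
  }
  stopifnot(n_fish >= 1, hatch_month %in% 1:12,
            length(stage_mean_temps) == 3L,
            ar1_phi >= 0, ar1_phi < 1, ar1_sigma >= 0,
            iso_noise_d18o >= 0, iso_noise_d13c >= 0,
            base_increment_um > 0, growth_gain_um >= 0)
  p <- list(
    region_preset = region_preset, n_fish = as.integer(n_fish),
    hatch_month = as.integer(hatch_month),
    hatch_year = as.integer(hatch_year),
    stage_mean_temps = stage_mean_temps,
    ar1_phi = ar1_phi, ar1_sigma = ar1_sigma,
    envelope_true = envelope_true,
    base_increment_um = base_increment_um,
    growth_gain_um = growth_gain_um,
    sl_per_or = sl_per_or, or_first_um = or_first_um,
    iso_noise_d18o = iso_noise_d18o, iso_noise_d13c = iso_noise_d13c,
    jp_salinity = jp_salinity, seed = as.integer(seed)
  )
  class(p) <- "cohort_params"
  p
}

envelope_upper_eval <- function(env, t) {
  env$upper[["c0"]] + env$upper[["c1"]] * t + env$upper[["c2"]] * t^2
}

envelope_lower_eval <- function(env, t) {
  exp(env$lower[["eta0"]] + env$lower[["eta1"]] * t)
}

check_envelope <- function(env, t_range) {
  tt <- seq(t_range[1], t_range[2], by = 0.1)
  bad <- envelope_upper_eval(env, tt) <= envelope_lower_eval(env, tt)
  if (any(bad)) {
    stop(sprintf(
      "true envelope inverted (lower >= upper) at %.1f degC", tt[bad][1L]))
  }
  invisible(TRUE)
}

true_optimal_temperature <- function(env, t_range, grid_step = 0.01) {
  tt <- seq(t_range[1], t_range[2], by = grid_step)
  gap <- envelope_upper_eval(env, tt) - envelope_lower_eval(env, tt)
  tt[which.max(gap)]
}

#' Generate hydrographic surface observations for one month
#'
#' Emulates surface-layer Argo temperature/salinity pairs: salinity drawn
#' uniformly over `salinity_range`, temperature on a linear T-S relation plus
#' Gaussian scatter. With zero scatter the pairs lie exactly on the relation.
#'
#' @param month Calendar month 1-12.
#' @param n_obs Number of observations (>= 3).
#' @param ts_slope,ts_intercept Linear T-S relation `T = ts_slope * S +
#'   ts_intercept` (degC, degC per salinity unit).
#' @param scatter_sd Gaussian scatter of temperature about the relation
#'   (degC, >= 0).
#' @param salinity_range Length-2 uniform sampling range for salinity.
#' @param year Calendar year tag.
#' @param seed Integer seed.
#' @return data.frame with columns `year`, `month`, `temp_c`, `salinity`.
#' @export
gen_hydro <- function(month, n_obs, ts_slope, ts_intercept, scatter_sd = 0,
                      salinity_range = c(32.8, 33.4), year = 2008, seed = 1) {
  if (!(month %in% 1:12)) stop("month must be in 1..12")
  if (n_obs < 3) stop("n_obs must be at least 3")
  if (scatter_sd < 0) stop("scatter_sd must be non-negative")
  set.seed(seed)
  s <- stats::runif(n_obs, salinity_range[1], salinity_range[2])
  t <- ts_slope * s + ts_intercept + stats::rnorm(n_obs, 0, scatter_sd)
  data.frame(year = year, month = as.integer(month), temp_c = t, salinity = s)
}

#' Generate a synthetic otolith cohort with known ground truth
#'
#' Forward-simulates, per fish: a daily AR(1) temperature trajectory around
#' the stage means; per milled interval a true metabolic fraction `M_true`
#' drawn uniformly between the true lower and upper envelope bounds at the
#' interval-mean temperature; daily increment widths `base + gain * (M_true -
#' lower(T))`; interval otolith d18O through the forward fractionation line at
#' the region's seawater d18O (plus the 0.09 permil acid-fractionation offset
#' for intervals measured on the automated 72 degC line, so generated values
#' are as-measured); and interval d13C from the mixing model at midpoint
#' diet/DIC values. Gaussian measurement noise is added to both isotopes.
#'
#' @param params A [cohort_params()] object.
#' @return A list with `otoliths` (fish_id, region, dph, increment_um),
#'   `isotopes` (fish_id, interval bounds, d13c_vpdb, d18o_vpdb, instrument),
#'   `fish` (catch metadata incl. hatch_date, sl_catch_mm, or_catch_um),
#'   and `truth` (per-fish daily temperatures, per-interval `t_mean_true` and
#'   `m_true`, the true optimal temperature `t_opt_true`, and the seed).
#' @export
gen_fish_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  preset <- region_preset(params$region_preset)
  env <- params$envelope_true
  t_check <- range(params$stage_mean_temps) + c(-5, 5)
  check_envelope(env, t_check)

  intervals <- preset$milled_intervals
  last_day <- max(intervals[, "end_dph"])
  sw <- preset$stage_windows
  # stage mean per day 0..last_day; beyond the last stage keep its mean
  day_stage <- findInterval(0:last_day, c(sw$start_dph, Inf))
  day_stage[day_stage > 3L] <- 3L
  mu_day <- params$stage_mean_temps[day_stage]

  sw_d18o <- if (preset$sw_rule == "fixed") preset$sw_d18o_fixed else
    sw_d18o_from_salinity(params$jp_salinity, preset$sw_calibration)
  diet_mid <- mean(preset$d13c_diet_range)
  dic_mid <- mean(preset$d13c_dic_range)
  hatch_date <- as.Date(sprintf("%04d-%02d-15",
                                params$hatch_year, params$hatch_month))
  n_int <- nrow(intervals)
  # first (core-nearest) interval measured on the 25 degC micro-volume line
  instrument <- c("micro25C", rep("auto72C", n_int - 1L))

  oto_list <- vector("list", params$n_fish)
  iso_list <- vector("list", params$n_fish)
  fish_list <- vector("list", params$n_fish)
  temps_true <- matrix(NA_real_, nrow = params$n_fish, ncol = last_day + 1L)
  truth_int <- vector("list", params$n_fish)
  n_floored <- 0L

  for (f in seq_len(params$n_fish)) {
    set.seed(.counter_seed(params$seed, f))
    fish_id <- sprintf("%s_%04d", params$region_preset, f)
    # AR(1) deviations around the stage means
    e <- numeric(last_day + 1L)
    e[1] <- stats::rnorm(1, 0, if (params$ar1_phi < 1)
      params$ar1_sigma / sqrt(1 - params$ar1_phi^2) else params$ar1_sigma)
    if (last_day > 0) {
      innov <- stats::rnorm(last_day, 0, params$ar1_sigma)
      for (d in 2:(last_day + 1L)) {
        e[d] <- params$ar1_phi * e[d - 1L] + innov[d - 1L]
      }
    }
    temp_day <- mu_day + e
    temps_true[f, ] <- temp_day

    t_mean <- apply(intervals, 1, function(iv) {
      mean(temp_day[(iv[1]:iv[2]) + 1L])
    })
    lo <- envelope_lower_eval(env, t_mean)
    up <- envelope_upper_eval(env, t_mean)
    if (any(up <= lo)) {
      stop(sprintf("true envelope inverted at %.2f degC", t_mean[up <= lo][1]))
    }
    m_true <- stats::runif(n_int, lo, up)

    # daily widths: interval-constant scope signal
    width_day <- rep(NA_real_, last_day + 1L)
    for (i in seq_len(n_int)) {
      days <- intervals[i, 1]:intervals[i, 2]
      width_day[days + 1L] <- params$base_increment_um +
        params$growth_gain_um * (m_true[i] - lo[i])
    }
    first <- preset$first_increment_dph
    widths <- width_day[(first:last_day) + 1L]
    floored <- widths <= 0
    if (any(floored)) {
      widths[floored] <- 0.1
      n_floored <- n_floored + sum(floored)
    }
    or_catch <- params$or_first_um + sum(widths)
    sl_catch <- preset$sl_first_mm +
      params$sl_per_or * (or_catch - params$or_first_um)

    d18o <- forward_otolith_d18o(sw_d18o, t_mean) +
      0.09 * (instrument == "auto72C") +
      stats::rnorm(n_int, 0, params$iso_noise_d18o)
    d13c <- dic_mid + m_true * (diet_mid - dic_mid) +
      stats::rnorm(n_int, 0, params$iso_noise_d13c)

    oto_list[[f]] <- data.frame(
      fish_id = fish_id, region = params$region_preset,
      dph = first:last_day, increment_um = widths,
      stringsAsFactors = FALSE)
    iso_list[[f]] <- data.frame(
      fish_id = fish_id,
      interval_start_dph = intervals[, "start_dph"],
      interval_end_dph = intervals[, "end_dph"],
      d13c_vpdb = d13c, d18o_vpdb = d18o, instrument = instrument,
      stringsAsFactors = FALSE)
    fish_list[[f]] <- data.frame(
      fish_id = fish_id, region = params$region_preset,
      hatch_date = hatch_date, sl_catch_mm = sl_catch,
      or_catch_um = or_catch, or_first_um = params$or_first_um,
      first_increment_dph = first, stringsAsFactors = FALSE)
    truth_int[[f]] <- data.frame(
      fish_id = fish_id,
      interval_start_dph = intervals[, "start_dph"],
      interval_end_dph = intervals[, "end_dph"],
      t_mean_true = t_mean, m_true = m_true, stringsAsFactors = FALSE)
  }
  if (n_floored > 0) {
    warning(sprintf("%d non-positive increment width(s) floored at 0.1 um",
                    n_floored))
  }
  list(
    otoliths = do.call(rbind, oto_list),
    isotopes = do.call(rbind, iso_list),
    fish = do.call(rbind, fish_list),
    truth = list(
      daily_temps = temps_true,
      intervals = do.call(rbind, truth_int),
      t_opt_true = true_optimal_temperature(env, t_check),
      sw_d18o = sw_d18o,
      d13c_diet_mid = diet_mid, d13c_dic_mid = dic_mid,
      seed = params$seed
    )
  )
}

#' Generate a synthetic stock-recruit series with a temperature effect
#'
#' `R_t = S_t * exp(a + b * S_t + temp_effect * x_t + eps_t)` with
#' `eps_t ~ N(0, sigma^2)` and `x_t` a standardized temperature anomaly
#' series. Spawning stock biomass is lognormal-AR(1), hence always positive
#' by construction.
#'
#' @param a,b Ricker coefficients (unitless; per unit biomass).
#' @param temp_effect Survival log-effect per standardized anomaly unit.
#' @param sigma Lognormal recruitment noise SD (>= 0).
#' @param n_years Series length (>= 5).
#' @param s_mean Mean spawning stock biomass level.
#' @param s_phi,s_sigma AR(1) parameters for log biomass.
#' @param start_year First calendar year.
#' @param seed Integer seed.
#' @return A list with `stock` (year, ssb, recruits), `anomaly`
#'   (year, anomaly; mean 0, SD 1) and the generative parameters.
#' @export
gen_stock_recruit <- function(a, b, temp_effect = 0, sigma = 0.3,
                              n_years = 30, s_mean = 1000,
                              s_phi = 0.8, s_sigma = 0.3,
                              start_year = 1980, seed = 1) {
  if (n_years < 5) stop("n_years must be at least 5")
  if (sigma < 0) stop("sigma must be non-negative")
  set.seed(seed)
  u <- numeric(n_years)
  u[1] <- stats::rnorm(1, 0, s_sigma / sqrt(1 - s_phi^2))
  for (t in seq_len(n_years - 1L)) {
    u[t + 1L] <- s_phi * u[t] + stats::rnorm(1, 0, s_sigma)
  }
  ssb <- s_mean * exp(u)
  x <- stats::rnorm(n_years)
  # decorrelate the anomaly series from the biomass regressors in sample so
  # the temperature signal is not confounded with density dependence, then
  # standardize to mean 0, SD 1
  x <- stats::resid(stats::lm(x ~ ssb))
  x <- as.numeric(scale(x))
  eps <- if (sigma > 0) stats::rnorm(n_years, 0, sigma) else numeric(n_years)
  recruits <- ssb * exp(a + b * ssb + temp_effect * x + eps)
  years <- start_year + seq_len(n_years) - 1L
  list(
    stock = data.frame(year = years, ssb = ssb, recruits = recruits),
    anomaly = data.frame(year = years, anomaly = x),
    params = list(a = a, b = b, temp_effect = temp_effect, sigma = sigma,
                  seed = seed)
  )
}
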