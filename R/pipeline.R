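# Orchestration: CSV bundle I/O with schema validation, and the end-to-end
# pipeline backcalc -> moto -> temperature -> scope -> growthreg -> lnrr.
# All tables are plain CSV (UTF-8, header row, '.' decimal) with a comment
# header carrying the seed and config hash for provenance.

.write_csv_stamped <- function(df, path, seed, config_hash) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# otolife seed=%s config=%s", seed, config_hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
}

.read_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config[order(names(config))], tf)
  unname(tools::md5sum(tf))
}

#' Write a simulated cohort bundle to CSV
#'
#' Writes `otoliths.csv`, `isotopes.csv`, `fish.csv`, `truth.csv` and, when
#' given, `hydro.csv`, `stock.csv`, `anomaly.csv` into a directory. Every
#' file starts with a `#` comment line carrying the generator seed.
#'
#' @param cohort Output of [gen_fish_cohort()].
#' @param dir Output directory (created if missing).
#' @param hydro Optional data.frame from [gen_hydro()] (rows of several
#'   months may be bound together).
#' @param stock_recruit Optional output of [gen_stock_recruit()].
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(cohort, dir, hydro = NULL, stock_recruit = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cohort$truth$seed
  h <- .config_hash(list(seed = seed))
  truth_df <- cohort$truth$intervals
  truth_df$t_opt_true <- cohort$truth$t_opt_true
  files <- c(
    otoliths = file.path(dir, "otoliths.csv"),
    isotopes = file.path(dir, "isotopes.csv"),
    fish = file.path(dir, "fish.csv"),
    truth = file.path(dir, "truth.csv")
  )
  .write_csv_stamped(cohort$otoliths, files["otoliths"], seed, h)
  .write_csv_stamped(cohort$isotopes, files["isotopes"], seed, h)
  .write_csv_stamped(cohort$fish, files["fish"], seed, h)
  .write_csv_stamped(truth_df, files["truth"], seed, h)
  if (!is.null(hydro)) {
    files <- c(files, hydro = file.path(dir, "hydro.csv"))
    .write_csv_stamped(hydro, files["hydro"], seed, h)
  }
  if (!is.null(stock_recruit)) {
    files <- c(files, stock = file.path(dir, "stock.csv"),
               anomaly = file.path(dir, "anomaly.csv"))
    .write_csv_stamped(stock_recruit$stock, files["stock"], seed, h)
    .write_csv_stamped(stock_recruit$anomaly, files["anomaly"], seed, h)
  }
  invisible(files)
}

.violation <- function(file, row, id, message) {
  data.frame(file = file, row = row, id = id, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a CSV input bundle against the pipeline schemas
#'
#' Checks column presence and the scientific invariants: positive increment
#' widths, per-fish monotone ages, non-overlapping ordered milled intervals,
#' salinity and temperature bounds for hydrographic rows, and positive
#' biomass/recruitment. Every violation is reported with its file, row and
#' identifier.
#'
#' @param paths Named character vector or list; recognised names are
#'   `otoliths`, `isotopes`, `fish`, `hydro`, `stock`.
#' @return data.frame of violations (zero rows when the bundle is clean).
#' @export
validate_tables <- function(paths) {
  v <- list()
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      v[[length(v) + 1L]] <<- .violation(
        file, NA_integer_, NA_character_,
        paste("missing column(s):", paste(miss, collapse = ", ")))
      FALSE
    } else TRUE
  }
  if (!is.null(paths[["otoliths"]])) {
    oto <- .read_csv(paths[["otoliths"]])
    if (need(oto, c("fish_id", "dph", "increment_um"), "otoliths")) {
      bad <- which(!is.finite(oto$increment_um) | oto$increment_um <= 0)
      for (i in bad) {
        v[[length(v) + 1L]] <- .violation(
          "otoliths", i, oto$fish_id[i], "non-positive increment width")
      }
      for (fid in unique(oto$fish_id)) {
        d <- oto$dph[oto$fish_id == fid]
        if (any(diff(d) != 1)) {
          v[[length(v) + 1L]] <- .violation(
            "otoliths", NA_integer_, fid,
            "dph not consecutive (gaps or non-monotone ages)")
        }
      }
    }
  }
  if (!is.null(paths[["isotopes"]])) {
    iso <- .read_csv(paths[["isotopes"]])
    if (need(iso, c("fish_id", "interval_start_dph", "interval_end_dph",
                    "d13c_vpdb", "d18o_vpdb"), "isotopes")) {
      for (fid in unique(iso$fish_id)) {
        ii <- iso[iso$fish_id == fid, ]
        ii <- ii[order(ii$interval_start_dph), ]
        if (any(ii$interval_end_dph < ii$interval_start_dph)) {
          v[[length(v) + 1L]] <- .violation(
            "isotopes", NA_integer_, fid, "interval end before start")
        }
        if (nrow(ii) > 1 &&
            any(ii$interval_start_dph[-1] <= ii$interval_end_dph[-nrow(ii)])) {
          v[[length(v) + 1L]] <- .violation(
            "isotopes", NA_integer_, fid, "overlapping milled intervals")
        }
      }
    }
  }
  if (!is.null(paths[["fish"]])) {
    fish <- .read_csv(paths[["fish"]])
    need(fish, c("fish_id", "region", "hatch_date", "sl_catch_mm",
                 "or_catch_um", "or_first_um", "first_increment_dph"), "fish")
  }
  if (!is.null(paths[["hydro"]])) {
    hyd <- .read_csv(paths[["hydro"]])
    if (need(hyd, c("year", "month", "temp_c", "salinity"), "hydro")) {
      bad <- which(hyd$temp_c < -2 | hyd$temp_c > 35 |
                   hyd$salinity < 25 | hyd$salinity > 38)
      for (i in bad) {
        v[[length(v) + 1L]] <- .violation(
          "hydro", i, NA_character_, "temperature or salinity out of bounds")
      }
    }
  }
  if (!is.null(paths[["stock"]])) {
    st <- .read_csv(paths[["stock"]])
    if (need(st, c("year", "ssb", "recruits"), "stock")) {
      bad <- which(st$ssb <= 0 | st$recruits <= 0)
      for (i in bad) {
        v[[length(v) + 1L]] <- .violation(
          "stock", i, as.character(st$year[i]),
          "non-positive biomass or recruitment")
      }
    }
  }
  if (length(v)) do.call(rbind, v) else
    .violation(character(), integer(), character(), character())[0, ]
}

#' Run the full reconstruction pipeline on a CSV bundle
#'
#' Executes, in order: schema validation, back-calculation, M_oto estimation
#' (Monte Carlo plus stage averaging with outlier exclusion), thermometry
#' (fixed-seawater or monthly quadratic depending on the region preset),
#' aerobic-scope envelopes per life stage, temperature-growth regressions
#' with Benjamini-Hochberg correction, and (when stock data are present) the
#' Ricker survival index. Outputs are CSV/JSON files plus a manifest; the run
#' is deterministic given identical inputs and seed.
#'
#' @param input_dir Directory holding the input bundle (as written by
#'   [write_simulation()]).
#' @param output_dir Directory for outputs (created if missing).
#' @param region `"JP"` or `"CA"`.
#' @param seed Integer seed for the Monte Carlo stages.
#' @param n_draws Monte Carlo draws for per-interval M_oto and length
#'   uncertainties.
#' @param stages Character vector of stages to run (consuming prior outputs
#'   is not needed: earlier stages are cheap and always recomputed in
#'   memory; this selects which outputs are written).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(input_dir, output_dir, region = c("JP", "CA"),
                         seed = 1, n_draws = 2000,
                         stages = c("backcalc", "moto", "temperature",
                                    "scope", "growthreg", "lnrr")) {
  region <- match.arg(region)
  stages <- match.arg(stages, several.ok = TRUE)
  preset <- region_preset(region)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    otoliths = file.path(input_dir, "otoliths.csv"),
    isotopes = file.path(input_dir, "isotopes.csv"),
    fish = file.path(input_dir, "fish.csv")
  )
  for (opt in c("hydro", "stock", "anomaly")) {
    p <- file.path(input_dir, paste0(opt, ".csv"))
    if (file.exists(p)) paths[[opt]] <- p
  }
  miss <- !vapply(paths[c("otoliths", "isotopes", "fish")], file.exists,
                  logical(1))
  if (any(miss)) {
    stop("missing input file(s): ",
         paste(names(paths[c("otoliths", "isotopes", "fish")])[miss],
               collapse = ", "))
  }
  viol <- validate_tables(paths[setdiff(names(paths), "anomaly")])
  if (nrow(viol)) {
    stop("input validation failed:\n",
         paste(utils::capture.output(print(viol)), collapse = "\n"))
  }
  config <- list(region = region, seed = seed, n_draws = n_draws,
                 stages = stages)
  h <- .config_hash(config)
  oto <- .read_csv(paths$otoliths)
  iso <- .read_csv(paths$isotopes)
  fish <- .read_csv(paths$fish)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("otolife")),
                   region = region, seed = seed, n_draws = n_draws,
                   config_hash = h, counts = list(), warnings = list())
  fids <- unique(fish$fish_id)

  # --- backcalc ---------------------------------------------------------
  bc_list <- lapply(seq_along(fids), function(i) {
    fid <- fids[i]
    frow <- fish[fish$fish_id == fid, ][1, ]
    widths <- oto$increment_um[oto$fish_id == fid][
      order(oto$dph[oto$fish_id == fid])]
    res <- backcalc_profile(widths, frow$sl_catch_mm, frow$or_first_um,
                            region, or_catch = frow$or_catch_um,
                            n_draws = n_draws,
                            seed = .counter_seed(seed, i))
    cbind(fish_id = fid, res, stringsAsFactors = FALSE)
  })
  backcalc <- do.call(rbind, bc_list)
  manifest$counts$backcalc <- nrow(backcalc)
  if ("backcalc" %in% stages) {
    .write_csv_stamped(backcalc, file.path(output_dir, "backcalc.csv"),
                       seed, h)
  }

  # --- moto -------------------------------------------------------------
  ctx <- isotope_context(region)
  mc <- mc_moto(iso$d13c_vpdb, ctx, n_draws = max(100, n_draws), seed = seed)
  moto_df <- data.frame(
    fish_id = iso$fish_id,
    interval_start_dph = iso$interval_start_dph,
    interval_end_dph = iso$interval_end_dph,
    moto = mc$moto_mean, moto_sd = mc$moto_sd, stringsAsFactors = FALSE)
  stage_res <- withCallingHandlers(
    stage_average_moto(moto_df, region),
    warning = function(w) {
      manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  manifest$counts$moto <- nrow(moto_df)
  manifest$counts$moto_outliers <- sum(stage_res$stage_means$outlier)
  if ("moto" %in% stages) {
    out <- moto_df
    mid <- floor((out$interval_start_dph + out$interval_end_dph) / 2)
    out$stage <- assign_stage(mid, region)
    key <- paste(out$fish_id, out$stage)
    flagged <- with(stage_res$stage_means,
                    paste(fish_id, stage)[outlier])
    out$outlier_flag <- key %in% flagged
    .write_csv_stamped(out, file.path(output_dir, "moto.csv"), seed, h)
  }

  # --- temperature ------------------------------------------------------
  thermometers <- NULL
  if (preset$thermometry_mode == "monthly") {
    if (is.null(paths$hydro)) {
      stop("stage temperature: monthly thermometry needs hydro.csv")
    }
    hyd <- .read_csv(paths$hydro)
    thermometers <- vector("list", 12L)
    for (m in sort(unique(hyd$month))) {
      thermometers[[m]] <- build_monthly_thermometer(
        hyd[hyd$month == m, ], preset$sw_calibration, month = m)
    }
  }
  temp_list <- lapply(fids, function(fid) {
    frow <- fish[fish$fish_id == fid, ][1, ]
    ii <- iso[iso$fish_id == fid, ]
    th <- thermal_history(
      ii, mode = preset$thermometry_mode,
      hatch_date = frow$hatch_date, thermometers = thermometers,
      d18o_sw = if (preset$sw_rule == "fixed") preset$sw_d18o_fixed else -0.32)
    cbind(fish_id = fid, th, stringsAsFactors = FALSE)
  })
  temps <- do.call(rbind, temp_list)
  manifest$counts$temperature <- nrow(temps)
  if ("temperature" %in% stages) {
    .write_csv_stamped(temps, file.path(output_dir, "temps.csv"), seed, h)
  }

  # --- scope ------------------------------------------------------------
  scope_out <- list()
  if ("scope" %in% stages) {
    mid <- floor((temps$interval_start_dph + temps$interval_end_dph) / 2)
    temps$stage <- assign_stage(mid, region)
    tstage <- stats::aggregate(
      list(temp_c = temps$temp_c),
      by = list(fish_id = temps$fish_id, stage = temps$stage), FUN = mean)
    joined <- merge(stage_res$retained, tstage, by = c("fish_id", "stage"))
    for (s in unique(joined$stage)) {
      sub <- joined[joined$stage == s, ]
      env <- tryCatch(
        estimate_scope_envelope(sub$temp_c, sub$moto),
        error = function(e) conditionMessage(e),
        warning = function(w) conditionMessage(w))
      scope_out[[s]] <- if (inherits(env, "scope_envelope")) {
        list(t_opt = env$t_opt, upper = as.list(env$upper),
             lower = as.list(env$lower), n_bins = nrow(env$bins),
             range = env$range)
      } else list(error = env)
    }
    jsonlite::write_json(
      scope_out, file.path(output_dir, "scope.json"),
      auto_unbox = TRUE, digits = NA)
    manifest$counts$scope_stages <- length(scope_out)
  }

  # --- growthreg --------------------------------------------------------
  if ("growthreg" %in% stages) {
    sw <- preset$stage_windows
    mid <- floor((temps$interval_start_dph + temps$interval_end_dph) / 2)
    tests <- list()
    for (i in seq_len(nrow(sw))) {
      end_age <- sw$end_dph[i]
      sl_end <- backcalc[backcalc$dph == end_age,
                         c("fish_id", "sl_mm"), drop = FALSE]
      tsub <- temps[mid <= end_age, ]
      tmean <- stats::aggregate(list(temp_c = tsub$temp_c),
                                by = list(fish_id = tsub$fish_id), FUN = mean)
      m <- merge(sl_end, tmean, by = "fish_id")
      if (nrow(m) >= 5 && stats::var(m$temp_c) > 0) {
        pr <- pearson_with_p(m$temp_c, m$sl_mm)
        ch <- quadratic_term_selection(m$sl_mm, m$temp_c)
        tests[[sw$stage[i]]] <- list(
          end_dph = end_age, n = pr$n, r = pr$r, p = pr$p,
          chosen_model = ch$chosen, aic = as.list(ch$aic))
      }
    }
    if (length(tests)) {
      bh <- bh_adjust(vapply(tests, `[[`, numeric(1), "p"))
      for (i in seq_along(tests)) {
        tests[[i]]$p_adjusted <- bh$adjusted[i]
        tests[[i]]$significant <- bh$reject[i]
      }
    }
    jsonlite::write_json(tests, file.path(output_dir, "growthreg.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$counts$growthreg_tests <- length(tests)
  }

  # --- lnrr -------------------------------------------------------------
  if ("lnrr" %in% stages && !is.null(paths$stock)) {
    st <- .read_csv(paths$stock)
    co <- fit_ricker(st$ssb, st$recruits)
    res <- lnrr(st$ssb, st$recruits, co)
    out <- data.frame(year = st$year, ssb = st$ssb, recruits = st$recruits,
                      lnrr = res)
    .write_csv_stamped(out, file.path(output_dir, "lnrr.csv"), seed, h)
    stats_block <- list(a = co[["a"]], b = co[["b"]])
    if (!is.null(paths$anomaly)) {
      an <- .read_csv(paths$anomaly)
      cs <- correlate_survival_with_anomaly(st, an)
      stats_block$r <- cs$r
      stats_block$p <- cs$p
      stats_block$n <- cs$n
    }
    jsonlite::write_json(stats_block, file.path(output_dir, "lnrr_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$counts$lnrr_years <- nrow(out)
  }

  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
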