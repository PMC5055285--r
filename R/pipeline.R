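#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs: the sites, the synthetic
#' generator (or paths to existing series CSVs), the models to score, the
#' category scheme and heat-budget parameters, and output options. The
#' experiment seed overrides the generator seed; per-site generator seeds are
#' derived as `seed + 101 * (site_index - 1)`.
#'
#' @param sites A list of [site_config()] objects (>= 1).
#' @param generator A [generator_config()], or a list of per-site lists with
#'   elements `env` and `loggers` (paths to CSVs in the package dialect).
#' @param models Character subset of `c("air_proxy", "elvin_gonor",
#'   "site_regression", "heat_budget")`.
#' @param scheme A [category_scheme()].
#' @param heat_budget_params A [heat_budget_params()] list used by the
#'   heat-budget forecast model.
#' @param in_sample If TRUE the site regression is fitted and scored on all
#'   days; default FALSE fits on the chronological first half of days and
#'   scores only the second half.
#' @param output_dir Optional directory for CSV outputs and the run log.
#' @param seed Integer master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(sites = list(site_config()),
                              generator = generator_config(),
                              models = c("air_proxy", "elvin_gonor",
                                         "site_regression", "heat_budget"),
                              scheme = category_scheme(),
                              heat_budget_params = musselskill::heat_budget_params(),
                              in_sample = FALSE,
                              output_dir = NULL,
                              seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  if (length(sites) < 1L) stop("need at least one site")
  if (length(models) < 1L) stop("need at least one model")
  structure(list(sites = sites, generator = generator, models = models,
                 scheme = scheme, heat_budget_params = heat_budget_params,
                 in_sample = in_sample, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

model_forecast <- function(model, env_h, coeffs, hb_params) {
  switch(model,
    air_proxy = predict_air_proxy(env_h$air_temp),
    elvin_gonor = predict_elvin_gonor(env_h$air_temp, env_h$solar),
    site_regression = predict_site_regression(coeffs, env_h$air_temp,
                                              env_h$solar),
    heat_budget = steady_state_temperature(env_h$air_temp, env_h$solar,
                                           env_h$wind, hb_params))
}

hourly_env <- function(env) {
  cols <- setdiff(names(env), "time")
  out <- NULL
  for (nm in cols) {
    h <- hourly_average(env$time, env[[nm]])
    names(h)[2] <- nm
    out <- if (is.null(out)) h else dplyr::left_join(out, h, by = "time")
  }
  out
}

#' Run a full model-skill experiment
#'
#' For each site: obtain (or generate) environmental forcing and multi-logger
#' body-temperature truth, reduce everything to hourly means, mask emersion
#' via tide plus wave run-up against logger elevation, run every configured
#' forecast model, pair forecast and observed daily maxima, and score each
#' (site, model, logger) pairing with the full verification suite. Also
#' computes per-site pooled reports (all loggers' paired days pooled), the
#' inter-logger baseline, and cross-site mean/SD summary rows. Deterministic
#' for a fixed configuration and seed. A failed (site, model) combination is
#' recorded with its reason and the run continues.
#'
#' @param cfg An [experiment_config()].
#' @return A list of class `experiment_result` with elements `reports` (per
#'   site/model/logger tibble), `site_reports` (per site/model pooled),
#'   `summary` (cross-site mean and SD per model and metric), `baseline`
#'   (inter-logger tibble), `tables` (named list of pooled contingency
#'   tables), `failures` (tibble), `log` (character lines) and `seed`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  reports <- list(); site_reports <- list(); baselines <- list()
  tables <- list(); failures <- list()

  for (s_idx in seq_along(cfg$sites)) {
    site <- cfg$sites[[s_idx]]
    if (inherits(cfg$generator, "generator_config")) {
      gcfg <- cfg$generator
      gcfg$seed <- cfg$seed + 101L * (s_idx - 1L)
      env <- generate_environment(site, gcfg)
      loggers <- generate_truth_loggers(env, site, gcfg)
      runup_coeff <- gcfg$runup_coefficient
    } else {
      paths <- cfg$generator[[s_idx]]
      env <- read_series_csv(paths$env)
      loggers <- lapply(paths$loggers, read_series_csv)
      names(loggers) <- vapply(loggers, function(l) l$microsite_id[1],
                               character(1))
      runup_coeff <- 1
    }
    say("site %s: %d environmental records, %d loggers",
        site$site_id, nrow(env), length(loggers))

    env_h <- hourly_env(env)
    runup_h <- wave_runup(env_h$sig_wave_height, site$shore_slope, runup_coeff)
    emersed_h <- emersion_mask(env_h$tide_height, runup_h,
                               site$logger_elevation)
    loggers_h <- lapply(loggers, function(l) hourly_average(l$time, l$body_temp))
    loggers_h <- lapply(loggers_h, function(l) {
      names(l)[2] <- "body_temp"
      stopifnot(identical(l$time, env_h$time))
      l
    })
    say("site %s: %d hours, %d emersed", site$site_id, nrow(env_h),
        sum(emersed_h))

    dates_local <- as.Date(env_h$time + site$utc_offset * 3600, tz = "UTC")
    split_date <- sort(unique(dates_local))[ceiling(length(unique(dates_local)) / 2)]
    train_hours <- dates_local <= split_date

    for (model in cfg$models) {
      coeffs <- NULL
      if (model == "site_regression") {
        fit_mask <- emersed_h & (cfg$in_sample | train_hours)
        pooled_obs <- rowMeans(do.call(cbind,
                                       lapply(loggers_h, `[[`, "body_temp")),
                               na.rm = TRUE)
        coeffs <- tryCatch(
          fit_site_regression(env_h$air_temp, env_h$solar, pooled_obs,
                              emersed = fit_mask),
          error = function(e) e)
        if (inherits(coeffs, "error")) {
          failures[[length(failures) + 1L]] <- tibble::tibble(
            site = site$site_id, model = model,
            reason = conditionMessage(coeffs))
          say("site %s model %s FAILED: %s", site$site_id, model,
              conditionMessage(coeffs))
          next
        }
      }
      pred <- tryCatch(model_forecast(model, env_h, coeffs,
                                      cfg$heat_budget_params),
                       error = function(e) e)
      if (inherits(pred, "error")) {
        failures[[length(failures) + 1L]] <- tibble::tibble(
          site = site$site_id, model = model,
          reason = conditionMessage(pred))
        say("site %s model %s FAILED: %s", site$site_id, model,
            conditionMessage(pred))
        next
      }
      # out-of-sample: score the regression on held-out days only
      score_mask <- if (model == "site_regression" && !cfg$in_sample) {
        emersed_h & !train_hours
      } else emersed_h

      pooled_pairs <- list()
      for (lg in names(loggers_h)) {
        pairs <- daily_max_pairs(env_h$time, pred,
                                 loggers_h[[lg]]$body_temp,
                                 score_mask, site$utc_offset)
        if (nrow(pairs) == 0L) next
        rep_l <- skill_report(pairs, cfg$scheme)
        reports[[length(reports) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(site = site$site_id, model = model, logger = lg),
          skill_report_row(rep_l))
        pooled_pairs[[lg]] <- pairs
      }
      pooled <- dplyr::bind_rows(pooled_pairs)
      if (nrow(pooled) > 0L) {
        rep_s <- skill_report(pooled, cfg$scheme)
        site_reports[[length(site_reports) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(site = site$site_id, model = model),
          skill_report_row(rep_s))
        tables[[paste(site$site_id, model, sep = "_")]] <- rep_s$table
        say("site %s model %s: %d paired logger-days", site$site_id, model,
            nrow(pooled))
      }
    }

    if (length(loggers_h) >= 2L) {
      base <- interlogger_baseline(loggers_h, emersed_h, site$utc_offset,
                                   cfg$scheme)
      base <- dplyr::bind_cols(tibble::tibble(site = rep(site$site_id,
                                                         nrow(base))), base)
      baselines[[length(baselines) + 1L]] <- base
    }
  }

  reports <- dplyr::bind_rows(reports)
  site_reports <- dplyr::bind_rows(site_reports)
  baseline <- dplyr::bind_rows(baselines)
  failures <- dplyr::bind_rows(failures)

  summary <- NULL
  if (nrow(site_reports) > 0L) {
    metrics <- c("bias", "mae", "rmse", "heidke", "peirce", "gerrity")
    safe_sum <- function(x, which) {
      if (all(is.na(x))) return(NA_real_)
      summarize_across_sites(x)[[which]]
    }
    summary <- site_reports |>
      dplyr::group_by(.data$model) |>
      dplyr::summarise(dplyr::across(
        dplyr::all_of(metrics),
        list(mean = ~safe_sum(.x, "mean"),
             sd = ~safe_sum(.x, "sd"))), .groups = "drop")
  }

  result <- structure(list(reports = reports, site_reports = site_reports,
                           summary = summary, baseline = baseline,
                           tables = tables, failures = failures,
                           log = log_lines, seed = cfg$seed),
                      class = "experiment_result")
  if (!is.null(cfg$output_dir)) write_experiment(result, cfg$output_dir)
  if (nrow(failures) > 0L &&
      nrow(site_reports) == 0L) {
    stop("all configured (site, model) combinations failed")
  }
  result
}

#' Write experiment outputs as CSV
#'
#' Writes `reports.csv`, `site_reports.csv`, `summary.csv`, `baseline.csv`,
#' `failures.csv`, a `run_log.txt`, and one contingency-table CSV per pooled
#' (site, model) under `tables/`.
#'
#' @param result An `experiment_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$reports, file.path(dir, "reports.csv"))
  readr::write_csv(result$site_reports, file.path(dir, "site_reports.csv"))
  if (!is.null(result$summary)) {
    readr::write_csv(result$summary, file.path(dir, "summary.csv"))
  }
  if (nrow(result$baseline) > 0L) {
    readr::write_csv(result$baseline, file.path(dir, "baseline.csv"))
  }
  if (nrow(result$failures) > 0L) {
    readr::write_csv(result$failures, file.path(dir, "failures.csv"))
  }
  writeLines(result$log, file.path(dir, "run_log.txt"))
  tdir <- file.path(dir, "tables")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in names(result$tables)) {
    write_table_csv(result$tables[[nm]], file.path(tdir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment result: %d site-model reports, %d logger reports\n",
              nrow(x$site_reports), nrow(x$reports)))
  if (!is.null(x$summary)) {
    cat("Cross-site summary (mean over sites):\n")
    print(as.data.frame(x$summary), digits = 3)
  }
  invisible(x)
}
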