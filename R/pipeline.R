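#' Default pipeline configuration
#'
#' One nested list drives a whole run: design sizes, trace simulation (or
#' the location of logger CSVs), gap policy, classifier settings, windows,
#' and the model/bootstrap block. Any subset can be overridden from a YAML
#' file ([read_pipeline_config()]) or by argument.
#'
#' @param ... Named top-level sections overriding the defaults (merged
#'   recursively).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  base <- list(
    mode = "synthetic",  # "synthetic" or "csv"
    seed = 1L,
    out_dir = "equilying-results",
    design = list(n_horses = 10L, n_reps = 2L, start_date = "2022-03-01"),
    io = list(max_gap_s = 5L,
              dialect = list(timestamp_col = "timestamp",
                             accel_col = "y_acc_g", sep = ",", dec = ".")),
    classifier = list(threshold_g = -0.75, window_samples = 31L),
    windows = list(day = list(start = "08:30", end = "16:00"),
                   night = list(start = "17:00", end = "07:30")),
    trace = list(mean_standing_bout_s = 9000, mean_lying_bout_s = 1800,
                 bout_dist = "lognormal", sdlog = 0.6, noise_sd_g = 0.05),
    inputs = list(schedule_csv = NULL, trace_dir = NULL,
                  trace_pattern = "%s_%s.csv"),
    model = list(outcomes = c("n_bouts_per_h", "lying_h_per_h"),
                 offset = "auto", n_boot = 1000L, ci_level = 0.95,
                 terms = c("GLOBAL", "CONDITION", "WINDOW", "INTERACTION"))
  )
  deep_merge(base, list(...))
}

deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the [pipeline_config()] defaults;
#' everything else keeps its default.
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw)
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Fails fast (before any file I/O) on malformed settings such as an even
#' smoothing window.
#'
#' @param config A `pipeline_config`.
#' @return `config`, invisibly, or an error.
#' @export
validate_pipeline_config <- function(config) {
  classifier_config(config$classifier$threshold_g,
                    config$classifier$window_samples)
  stopifnot(config$mode %in% c("synthetic", "csv"),
            config$design$n_horses >= 1,
            config$design$n_reps >= 1,
            config$io$max_gap_s >= 0,
            config$model$n_boot >= 1,
            config$model$ci_level > 0, config$model$ci_level < 1)
  bad_terms <- setdiff(config$model$terms,
                       c("GLOBAL", "CONDITION", "WINDOW", "INTERACTION"))
  if (length(bad_terms) > 0) {
    stop("unknown model terms: ", paste(bad_terms, collapse = ", "),
         call. = FALSE)
  }
  if (config$mode == "csv" &&
      (is.null(config$inputs$schedule_csv) || is.null(config$inputs$trace_dir))) {
    stop("csv mode needs inputs$schedule_csv and inputs$trace_dir",
         call. = FALSE)
  }
  invisible(config)
}

period_trace <- function(config, horse_id, date, seed) {
  start <- as.POSIXct(paste(date, "08:00:00"), tz = "UTC")
  if (config$mode == "synthetic") {
    tp <- config$trace
    params <- trace_sim_params(
      mean_standing_bout_s = tp$mean_standing_bout_s,
      mean_lying_bout_s = tp$mean_lying_bout_s,
      bout_dist = tp$bout_dist, sdlog = tp$sdlog,
      noise_sd_g = tp$noise_sd_g, duration_s = 86400L)
    simulate_trace(params, seed = seed, start_time = start,
                   horse_id = horse_id)$series
  } else {
    d <- config$io$dialect
    path <- file.path(config$inputs$trace_dir,
                      sprintf(config$inputs$trace_pattern, horse_id,
                              format(as.Date(date))))
    read_logger_csv(path, logger_dialect(d$timestamp_col, d$accel_col,
                                         d$sep, d$dec), horse_id = horse_id)
  }
}

#' Run the full analysis pipeline
#'
#' Executes read (or simulate) -> gap-fill -> threshold classify ->
#' majority smooth -> bout segmentation -> day/night metrics -> mixed
#' model -> parametric-bootstrap tests and intervals, writing every
#' intermediate table, a results JSON, the effective config and a
#' per-stage log into `config$out_dir`. A rerun with the same config and
#' seed reproduces the outputs byte for byte.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with `schedule`, `metrics`, `bouts`, `fits`,
#'   `tests`, `contrasts` and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_add <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  set.seed(config$seed)

  # stage 1: schedule
  schedule <- if (config$mode == "csv") {
    read_schedule_csv(config$inputs$schedule_csv)
  } else {
    generate_schedule(config$design$n_horses, config$design$n_reps,
                      start_date = as.Date(config$design$start_date))
  }
  log_add("schedule: %d horse-periods, %d horses", nrow(schedule),
          length(unique(schedule$horse_id)))

  # per-period and per-model seeds drawn once so stages are decoupled
  period_seeds <- sample.int(.Machine$integer.max, nrow(schedule))
  n_terms <- length(config$model$terms)
  model_seeds <- sample.int(.Machine$integer.max,
                            length(config$model$outcomes) * (n_terms + 1L))

  # stage 2: traces -> posture -> bouts -> metrics
  cls <- classifier_config(config$classifier$threshold_g,
                           config$classifier$window_samples)
  win_day <- window_spec("DAY", config$windows$day$start,
                         config$windows$day$end)
  win_night <- window_spec("NIGHT", config$windows$night$start,
                           config$windows$night$end)
  bouts_all <- vector("list", nrow(schedule))
  metrics_all <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    series <- period_trace(config, schedule$horse_id[i], schedule$date[i],
                           period_seeds[i])
    series <- fill_short_gaps(series, config$io$max_gap_s)
    states <- smooth_majority(threshold_classify(series, cls), cls)
    bouts <- segment_bouts(states)
    metrics_all[[i]] <- period_metrics(states, schedule$date[i],
                                       condition = schedule$condition[i],
                                       windows = list(win_day, win_night))
    bouts_all[[i]] <- bouts
  }
  bouts <- do.call(rbind, bouts_all)
  metrics <- do.call(rbind, metrics_all)
  log_add("traces: %d periods classified, %d bouts, %d metric rows",
          nrow(schedule), nrow(bouts), nrow(metrics))

  # stage 3: models, tests, intervals
  fits <- list()
  tests <- list()
  contrasts <- list()
  si <- 0L
  for (oc in config$model$outcomes) {
    off <- if (identical(config$model$offset, "auto")) {
      default_offset(metrics, oc)
    } else {
      as.numeric(config$model$offset)
    }
    fit <- fit_lmm(metrics, oc, method = "REML", offset = off)
    fits[[oc]] <- fit
    tests[[oc]] <- lapply(stats::setNames(nm = config$model$terms),
                          function(tm) {
      pb_test(metrics, oc, tm, n_boot = config$model$n_boot,
              seed = model_seeds[si + match(tm, config$model$terms)],
              offset = off)
    })
    contrasts[[oc]] <- pb_confint(metrics, oc,
                                  n_boot = config$model$n_boot,
                                  seed = model_seeds[si + n_terms + 1L],
                                  level = config$model$ci_level,
                                  offset = off)
    si <- si + n_terms + 1L
    log_add("model %s: offset %.5g, logLik %.3f, %d terms tested", oc, off,
            fit$loglik, length(config$model$terms))
  }

  # stage 4: outputs
  paths <- list(
    schedule = file.path(config$out_dir, "schedule.csv"),
    bouts = file.path(config$out_dir, "bouts.csv"),
    metrics = file.path(config$out_dir, "metrics.csv"),
    results = file.path(config$out_dir, "results.json"),
    summary = file.path(config$out_dir, "summary.txt"),
    config = file.path(config$out_dir, "config.yaml"),
    log = file.path(config$out_dir, "log.txt")
  )
  write_schedule_csv(schedule, paths$schedule)
  write_metrics_csv(bouts, paths$bouts)
  write_metrics_csv(metrics, paths$metrics)
  results <- lapply(stats::setNames(nm = config$model$outcomes), function(oc) {
    fit <- fits[[oc]]
    list(
      offset = fit$offset,
      variance_components = list(horse = fit$sigma2_horse,
                                 date = fit$sigma2_date,
                                 residual = fit$sigma2_resid),
      loglik = fit$loglik,
      converged = fit$converged,
      p_values = lapply(tests[[oc]], function(t) t$p_value),
      contrasts = contrasts[[oc]]
    )
  })
  jsonlite::write_json(results, paths$results, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  writeLines(unlist(lapply(config$model$outcomes, function(oc) {
    ct <- contrasts[[oc]]
    c(sprintf("outcome %s:", oc),
      sprintf("  %s: by a factor of %.2f [%.2f-%.2f]", ct$name, ct$factor,
              ct$ci_low, ct$ci_high),
      sprintf("  p-values: %s",
              paste(sprintf("%s=%.3g", names(tests[[oc]]),
                            vapply(tests[[oc]], `[[`, numeric(1), "p_value")),
                    collapse = ", ")))
  })), paths$summary)
  yaml::write_yaml(config, paths$config)
  writeLines(log_lines, paths$log)

  invisible(list(schedule = schedule, metrics = metrics, bouts = bouts,
                 fits = fits, tests = tests, contrasts = contrasts,
                 paths = paths))
}
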