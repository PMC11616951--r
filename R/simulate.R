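#' Parameters of the alternating-renewal trace simulator
#'
#' Posture is simulated as an alternating renewal process: sojourns in
#' standing and lying alternate, each drawn from a state-specific
#' distribution. The defaults emulate a young stabled horse over 24 h:
#' standing bouts of 2.5 h and lying bouts of 30 min on average (a lying
#' fraction near 1/6, i.e. about 4 h recumbency per day), right-skewed
#' lognormal bout lengths, and a leg-mounted vertical-axis signal near
#' -1 g when the cannon bone is vertical (standing) and near 0 g when
#' horizontal (lying), with additive Gaussian sensor noise.
#'
#' @param mean_standing_bout_s,mean_lying_bout_s Mean sojourn times in
#'   seconds.
#' @param bout_dist `"lognormal"` (default; `sdlog` shapes the skew, the
#'   meanlog is derived so the mean is as requested) or `"exponential"`
#'   (useful for analytic checks).
#' @param sdlog Log-scale standard deviation of lognormal bout lengths.
#' @param standing_level_g,lying_level_g Mean signal level per state, in g.
#' @param noise_sd_g Standard deviation of the additive sensor noise, in g.
#' @param duration_s Trace length in seconds.
#' @param min_bout_s Lower bound, in seconds, applied to every drawn
#'   sojourn (1 by default; raise it to guarantee that no true bout is
#'   shorter than the smoothing window).
#' @return A `trace_sim_params` list.
#' @export
trace_sim_params <- function(mean_standing_bout_s = 9000,
                             mean_lying_bout_s = 1800,
                             bout_dist = c("lognormal", "exponential"),
                             sdlog = 0.6,
                             standing_level_g = -1.0,
                             lying_level_g = 0.0,
                             noise_sd_g = 0.05,
                             duration_s = 86400L,
                             min_bout_s = 1L) {
  bout_dist <- match.arg(bout_dist)
  stopifnot(mean_standing_bout_s > 0, mean_lying_bout_s > 0,
            noise_sd_g >= 0, duration_s >= 1, min_bout_s >= 1)
  if (!(standing_level_g < -0.75 && lying_level_g >= -0.75)) {
    stop("signal levels must straddle the -0.75 g classification threshold",
         call. = FALSE)
  }
  structure(list(mean_standing_bout_s = mean_standing_bout_s,
                 mean_lying_bout_s = mean_lying_bout_s,
                 bout_dist = bout_dist, sdlog = sdlog,
                 standing_level_g = standing_level_g,
                 lying_level_g = lying_level_g,
                 noise_sd_g = noise_sd_g,
                 duration_s = as.integer(duration_s),
                 min_bout_s = as.integer(min_bout_s)),
            class = "trace_sim_params")
}

draw_bout <- function(params, mean_s) {
  x <- switch(params$bout_dist,
    exponential = stats::rexp(1, rate = 1 / mean_s),
    lognormal = stats::rlnorm(1, meanlog = log(mean_s) - params$sdlog^2 / 2,
                              sdlog = params$sdlog)
  )
  max(params$min_bout_s, as.integer(round(x)))
}

#' Simulate a ground-truthed accelerometer trace
#'
#' Draws alternating standing/lying sojourns until `duration_s` is tiled
#' (the final sojourn is truncated), then emits per-second acceleration as
#' the state level plus Gaussian noise. The exact sojourn list is returned
#' alongside the trace so downstream recovery can be scored against truth.
#'
#' @param params A [trace_sim_params()].
#' @param seed Optional RNG seed.
#' @param start_time Timestamp of the first sample.
#' @param horse_id Identifier recorded on the trace.
#' @param initial_state `"STANDING"` (default) or `"LYING"`.
#' @return List with `series` (an [accel_series()]) and `truth`, a bout
#'   data frame with `state`, `start`, `end`, `duration_s`.
#' @export
simulate_trace <- function(params = trace_sim_params(), seed = NULL,
                           start_time = as.POSIXct("2022-03-01 08:00:00",
                                                   tz = "UTC"),
                           horse_id = "SIM", initial_state = "STANDING") {
  stopifnot(inherits(params, "trace_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  start_time <- as_utc_time(start_time)
  total <- params$duration_s
  state <- match(initial_state, posture_labels) - 1L  # 0 standing, 1 lying
  lens <- integer(0)
  states <- integer(0)
  filled <- 0L
  while (filled < total) {
    mean_s <- if (state == 0L) params$mean_standing_bout_s else params$mean_lying_bout_s
    len <- min(draw_bout(params, mean_s), total - filled)
    # a remainder shorter than min_bout_s is absorbed into this sojourn so
    # the truncated tail never violates the bout-length floor
    if (total - filled - len < params$min_bout_s) len <- total - filled
    lens <- c(lens, len)
    states <- c(states, state)
    filled <- filled + len
    state <- 1L - state
  }
  level <- ifelse(rep.int(states, lens) == 1L, params$lying_level_g,
                  params$standing_level_g)
  y <- level + if (params$noise_sd_g > 0) {
    stats::rnorm(total, 0, params$noise_sd_g)
  } else 0
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  truth <- data.frame(
    state = posture_labels[states + 1L],
    start = start_time + (starts - 1L),
    end = start_time + ends,
    duration_s = lens,
    stringsAsFactors = FALSE
  )
  list(series = accel_series(y, start_time, horse_id), truth = truth)
}

#' Default log-scale cell means of the outcome models
#'
#' Six cell means (3 daytime conditions x day/night) on the log scale,
#' encoding the magnitudes typical of young riding horses in training:
#' lying duration about 11.25-fold higher at night (0.25 h/h in the night
#' box vs. 0.022 h/h by day), bout rate 1.21-fold higher by day (0.36 vs.
#' 0.30 bouts/h), and a mild monotone increase from box to paddock-alone
#' to paddock-in-pairs (factors 1.08/1.17 for bouts, 1.39/1.38 for
#' duration), applied uniformly across day and night.
#'
#' @param outcome `"lying_h_per_h"` or `"n_bouts_per_h"`.
#' @return Named numeric vector of 6 log cell means, names
#'   `<CONDITION>.<WINDOW>`.
#' @export
default_cell_means <- function(outcome = c("lying_h_per_h", "n_bouts_per_h")) {
  outcome <- match.arg(outcome)
  cond_factors <- switch(outcome,
    lying_h_per_h = c(BOX = 1, ALONE = 1.39, PAIRS = 1.38),
    n_bouts_per_h = c(BOX = 1, ALONE = 1.08, PAIRS = 1.17)
  )
  base <- switch(outcome,
    lying_h_per_h = c(DAY = 0.25 / 11.25, NIGHT = 0.25),
    n_bouts_per_h = c(DAY = 0.30 * 1.21, NIGHT = 0.30)
  )
  out <- log(outer(cond_factors, base))
  stats::setNames(as.vector(out),
                  as.vector(outer(names(cond_factors), names(base),
                                  paste, sep = ".")))
}

#' Parameters of the experiment-level outcome simulator
#'
#' Generates outcome tables exactly under the model the analysis assumes:
#' on the log scale, cell mean + horse random intercept + calendar-date
#' random intercept + residual, all Gaussian. Default variance components
#' reflect the large day-to-day variability seen in young horses (most
#' variance residual, a moderate horse component, a smaller shared-date
#' component).
#'
#' @param cell_means Named vector as from [default_cell_means()].
#' @param sigma2_horse,sigma2_date,sigma2_resid Variance components on the
#'   log scale.
#' @param offset Offset `c` of the `log(y + c)` transform the cell means
#'   live on; outcomes are back-transformed with its inverse.
#' @param outcome Name of the outcome column to produce.
#' @return An `experiment_sim_params` list.
#' @export
experiment_sim_params <- function(cell_means = default_cell_means("lying_h_per_h"),
                                  sigma2_horse = 0.2, sigma2_date = 0.1,
                                  sigma2_resid = 0.5, offset = 0,
                                  outcome = "lying_h_per_h") {
  stopifnot(sigma2_horse >= 0, sigma2_date >= 0, sigma2_resid >= 0,
            offset >= 0, length(cell_means) == 6)
  expected <- as.vector(outer(condition_levels, window_levels, paste, sep = "."))
  if (!setequal(names(cell_means), expected)) {
    stop("cell_means must be named <CONDITION>.<WINDOW> over ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  structure(list(cell_means = cell_means[expected],
                 sigma2_horse = sigma2_horse, sigma2_date = sigma2_date,
                 sigma2_resid = sigma2_resid, offset = offset,
                 outcome = outcome),
            class = "experiment_sim_params")
}

#' Simulate an experiment-level outcome table
#'
#' For every horse-period of the schedule, emits a day row and a night row
#' (night attributed to the evening's date): the log-scale outcome is the
#' condition-by-window cell mean plus the horse effect, the date effect
#' and residual noise, back-transformed through the inverse of the model's
#' `log(y + c)`.
#'
#' @param schedule A `crossover_schedule` from [generate_schedule()].
#' @param params An [experiment_sim_params()].
#' @param seed Optional RNG seed.
#' @return A metrics-style data frame (`horse_id`, `date`, `condition`,
#'   `window`, outcome column, `observed_h`) with the simulation truth
#'   (cell means, variances, realized effects) in `attr(, "truth")`.
#' @export
simulate_experiment <- function(schedule, params = experiment_sim_params(),
                                seed = NULL) {
  stopifnot(inherits(params, "experiment_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  horses <- sort(unique(schedule$horse_id))
  dates <- sort(unique(schedule$date))
  u_horse <- stats::setNames(
    stats::rnorm(length(horses), 0, sqrt(params$sigma2_horse)), horses)
  u_date <- stats::setNames(
    stats::rnorm(length(dates), 0, sqrt(params$sigma2_date)),
    as.character(dates))

  base <- schedule[rep(seq_len(nrow(schedule)), each = 2), ]
  base$window <- rep(window_levels, nrow(schedule))
  cell <- paste(base$condition, base$window, sep = ".")
  eta <- params$cell_means[cell] +
    u_horse[base$horse_id] +
    u_date[as.character(base$date)] +
    stats::rnorm(nrow(base), 0, sqrt(params$sigma2_resid))
  y <- pmax(exp(eta) - params$offset, 0)

  out <- data.frame(
    horse_id = base$horse_id,
    date = base$date,
    condition = base$condition,
    window = base$window,
    observed_h = ifelse(base$window == "DAY", day_window()$length_h,
                        night_window()$length_h),
    stringsAsFactors = FALSE
  )
  out[[params$outcome]] <- unname(y)
  rownames(out) <- NULL
  attr(out, "truth") <- list(cell_means = params$cell_means,
                             sigma2_horse = params$sigma2_horse,
                             sigma2_date = params$sigma2_date,
                             sigma2_resid = params$sigma2_resid,
                             u_horse = u_horse, u_date = u_date,
                             offset = params$offset)
  out
}
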