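#' Classifier settings: threshold and smoothing window
#'
#' Defaults reproduce the standard leg-logger rule for horses: a vertical
#' (Y-axis) acceleration below -0.75 g means the cannon bone is vertical
#' (standing, gravity on the axis), at or above it means the leg is
#' horizontal (lying). The per-second classification is then denoised with
#' a running median over 31 samples (31 s), which for a binary signal is a
#' majority vote over the window.
#'
#' @param threshold_g Decision threshold in g. Values `>= threshold_g`
#'   classify as lying, values below as standing.
#' @param window_samples Odd window length, in samples, of the majority
#'   filter.
#' @param sample_rate_hz Sampling rate; only 1 Hz is supported.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(threshold_g = -0.75, window_samples = 31L,
                              sample_rate_hz = 1) {
  window_samples <- as.integer(window_samples)
  if (is.na(window_samples) || window_samples < 1L ||
      window_samples %% 2L == 0L) {
    stop("window_samples must be an odd positive integer", call. = FALSE)
  }
  if (!identical(as.numeric(sample_rate_hz), 1)) {
    stop("only a 1 Hz sample rate is supported", call. = FALSE)
  }
  structure(list(threshold_g = as.numeric(threshold_g),
                 window_samples = window_samples, sample_rate_hz = 1),
            class = "classifier_config")
}

# internal coding: 0 = STANDING, 1 = LYING, NA = MISSING
posture_labels <- c("STANDING", "LYING")

new_posture_series <- function(states, start_time, horse_id) {
  structure(list(states = as.integer(states),
                 start_time = as_utc_time(start_time),
                 horse_id = as.character(horse_id)),
            class = "posture_series")
}

#' @exportS3Method
length.posture_series <- function(x) length(x$states)

#' @exportS3Method base::print
print.posture_series <- function(x, ...) {
  tab <- table(factor(posture_labels[x$states + 1L], levels = posture_labels),
               useNA = "no")
  cat(sprintf("<posture_series> horse %s, %d s: %d standing, %d lying, %d missing\n",
              x$horse_id, length(x), tab[["STANDING"]], tab[["LYING"]],
              sum(is.na(x$states))))
  invisible(x)
}

#' Posture states as character labels
#'
#' @param x A `posture_series`.
#' @return Character vector over `"STANDING"`, `"LYING"`, `NA`.
#' @export
posture_states <- function(x) posture_labels[x$states + 1L]

#' Threshold classification of a 1 Hz acceleration series
#'
#' Applies the per-sample rule only; no smoothing. Samples exactly on the
#' threshold belong to the lying class. Missing samples stay missing.
#'
#' @param series An [accel_series()].
#' @param config A [classifier_config()].
#' @return A `posture_series` aligned sample-for-sample with `series`.
#' @export
threshold_classify <- function(series, config = classifier_config()) {
  stopifnot(inherits(series, "accel_series"),
            inherits(config, "classifier_config"))
  states <- ifelse(series$y_accel >= config$threshold_g, 1L, 0L)
  new_posture_series(states, series$start_time, series$horse_id)
}

#' Running-median (majority-vote) smoothing of a posture series
#'
#' Each output state is the majority over the centred window of
#' `window_samples` input states; for a binary sequence this equals the
#' running median. At the series edges the window is truncated to the
#' available samples. Missing samples carry no vote; a tie (possible only
#' in truncated or missing-containing windows) resolves to standing, and a
#' window with no non-missing votes yields a missing state.
#'
#' @param states A `posture_series` from [threshold_classify()].
#' @param config A [classifier_config()]; only `window_samples` is used.
#' @return The smoothed `posture_series`.
#' @export
smooth_majority <- function(states, config = classifier_config()) {
  stopifnot(inherits(states, "posture_series"),
            inherits(config, "classifier_config"))
  s <- states$states
  n <- length(s)
  h <- (config$window_samples - 1L) %/% 2L
  lying_cum <- c(0L, cumsum(ifelse(is.na(s), 0L, s)))
  obs_cum <- c(0L, cumsum(!is.na(s)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  n_lying <- lying_cum[hi + 1L] - lying_cum[lo]
  n_obs <- obs_cum[hi + 1L] - obs_cum[lo]
  out <- ifelse(n_obs == 0L, NA_integer_,
                ifelse(2L * n_lying > n_obs, 1L, 0L))
  new_posture_series(out, states$start_time, states$horse_id)
}

#' Write a per-second posture CSV
#'
#' @param states A `posture_series`.
#' @param path Output path; columns `timestamp,state`.
#' @return `path`, invisibly.
#' @export
write_posture_csv <- function(states, path) {
  df <- data.frame(
    timestamp = format(series_timestamps(states), "%Y-%m-%dT%H:%M:%S",
                       tz = "UTC"),
    state = ifelse(is.na(states$states), "MISSING", posture_states(states)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
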