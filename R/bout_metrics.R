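#' Observation windows on the local clock
#'
#' The daytime window runs 08:30-16:00 (7.5 h) and the night window
#' 17:00-07:30 of the next day (14.5 h); the remaining hours are used to
#' move horses and are not scored. A night is attributed to the calendar
#' date of its evening.
#'
#' @param label `"DAY"` or `"NIGHT"`.
#' @param start_clock,end_clock Clock times `"HH:MM"`; a window whose end
#'   is at or before its start spans midnight.
#' @return A `window_spec` list with the window length in hours.
#' @export
window_spec <- function(label, start_clock, end_clock) {
  stopifnot(label %in% c("DAY", "NIGHT"))
  s <- clock_to_seconds(start_clock)
  e <- clock_to_seconds(end_clock)
  len <- if (e > s) e - s else 86400 - s + e
  if (len <= 0) stop("window length must be positive", call. = FALSE)
  structure(list(label = label, start_clock = start_clock,
                 end_clock = end_clock, length_h = len / 3600),
            class = "window_spec")
}

#' @rdname window_spec
#' @export
day_window <- function() window_spec("DAY", "08:30", "16:00")

#' @rdname window_spec
#' @export
night_window <- function() window_spec("NIGHT", "17:00", "07:30")

clock_to_seconds <- function(x) {
  p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(p) != 2 || anyNA(p)) stop("bad clock time: ", x, call. = FALSE)
  p[1] * 3600 + p[2] * 60
}

#' Absolute interval of a window occurrence on a given date
#'
#' @param window A [window_spec()].
#' @param date The calendar `Date` the occurrence is attributed to (for a
#'   night window, the evening's date).
#' @return `POSIXct` vector `c(start, end)`, end exclusive.
#' @export
window_interval <- function(window, date) {
  date <- as.Date(date)
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  s <- day0 + clock_to_seconds(window$start_clock)
  e <- day0 + clock_to_seconds(window$end_clock)
  if (e <= s) e <- e + 86400
  c(s, e)
}

#' Segment a smoothed posture series into bouts
#'
#' Maximal runs of one non-missing state become bouts; a missing run
#' terminates the current bout, so consecutive bouts of the same state can
#' occur across a dropout. Bouts tile the observed (non-missing) time
#' exactly.
#'
#' @param states A smoothed `posture_series`.
#' @return A data frame with columns `horse_id`, `state`, `start`, `end`
#'   (exclusive), `duration_s`, in time order; zero rows if the series is
#'   all missing.
#' @export
segment_bouts <- function(states) {
  stopifnot(inherits(states, "posture_series"))
  s <- states$states
  code <- ifelse(is.na(s), -1L, s)
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values >= 0L
  data.frame(
    horse_id = rep(states$horse_id, sum(keep)),
    state = posture_labels[r$values[keep] + 1L],
    start = states$start_time + (starts[keep] - 1L),
    end = states$start_time + ends[keep],
    duration_s = r$lengths[keep],
    stringsAsFactors = FALSE
  )
}

overlap_seconds <- function(starts, ends, iv) {
  pmax(0, as.numeric(pmin(ends, iv[2])) - as.numeric(pmax(starts, iv[1])))
}

#' Per-window lying metrics for one horse-period
#'
#' Bouts are clipped to the window occurrence; the per-hour denominator is
#' the observed (non-missing) time inside the window, which equals the
#' clipped total bout time because bouts tile observed time. A lying bout
#' with any positive overlap counts once towards the bout count.
#'
#' @param bouts Bout table from [segment_bouts()] for one horse-period.
#' @param window A [window_spec()].
#' @param date Calendar date of the window occurrence (evening's date for
#'   a night).
#' @param condition Daytime condition label carried into the output.
#' @param horse_id Horse identifier; defaults to the one on `bouts`.
#' @return One-row data frame: `horse_id`, `date`, `condition`, `window`,
#'   `n_bouts_per_h`, `lying_h_per_h`, `observed_h`.
#' @export
compute_metrics <- function(bouts, window, date, condition = NA_character_,
                            horse_id = NULL) {
  stopifnot(inherits(window, "window_spec"))
  if (is.null(horse_id)) {
    horse_id <- if (nrow(bouts) > 0) bouts$horse_id[1] else NA_character_
  }
  iv <- window_interval(window, date)
  ov <- if (nrow(bouts) > 0) {
    overlap_seconds(bouts$start, bouts$end, iv)
  } else {
    numeric(0)
  }
  observed_s <- sum(ov)
  if (observed_s <= 0) {
    stop(sprintf("zero observed hours in %s window of %s for horse %s",
                 window$label, as.Date(date), horse_id), call. = FALSE)
  }
  lying <- bouts$state == "LYING"
  lying_s <- sum(ov[lying])
  n_lying <- sum(ov > 0 & lying)
  observed_h <- observed_s / 3600
  data.frame(
    horse_id = horse_id,
    date = as.Date(date),
    condition = condition,
    window = window$label,
    n_bouts_per_h = n_lying / observed_h,
    lying_h_per_h = (lying_s / 3600) / observed_h,
    observed_h = observed_h,
    stringsAsFactors = FALSE
  )
}

#' Day and night metrics for one 24-h horse-period
#'
#' Convenience wrapper running [segment_bouts()] and [compute_metrics()]
#' for both windows of one recorded period.
#'
#' @param states A smoothed `posture_series` covering the period.
#' @param date Calendar date of the daytime observation.
#' @param condition Daytime condition label.
#' @param windows List of [window_spec()]s; defaults to day and night.
#' @return Data frame with one row per window.
#' @export
period_metrics <- function(states, date, condition = NA_character_,
                           windows = list(day_window(), night_window())) {
  bouts <- segment_bouts(states)
  do.call(rbind, lapply(windows, function(w) {
    compute_metrics(bouts, w, date, condition = condition,
                    horse_id = states$horse_id)
  }))
}

#' Write metrics and bout tables as CSV
#'
#' @param x Data frame from [compute_metrics()]/[period_metrics()] or
#'   [segment_bouts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(x, path) {
  df <- x
  for (col in intersect(c("start", "end"), names(df))) {
    df[[col]] <- format(df[[col]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
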