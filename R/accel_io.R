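#' Construct a 1 Hz acceleration series
#'
#' An `accel_series` holds the vertical-axis (Y) acceleration of one
#' leg-mounted logger for one horse-period, on a strict 1-second grid.
#' Missing seconds are explicit `NA`s, never silently dropped.
#'
#' @param y_accel Numeric vector of accelerations in g; `NA` marks a
#'   missing sample.
#' @param start_time `POSIXct` timestamp of the first sample (local clock;
#'   stored as UTC so no daylight-saving arithmetic is applied).
#' @param horse_id Identifier of the animal wearing the logger.
#' @param sample_rate_hz Sampling rate; only 1 Hz is supported.
#' @param n_filled Number of gap-filled samples (bookkeeping, see
#'   [fill_short_gaps()]).
#' @return An object of class `accel_series`.
#' @export
accel_series <- function(y_accel, start_time, horse_id = NA_character_,
                         sample_rate_hz = 1, n_filled = 0L) {
  stopifnot(is.numeric(y_accel), length(y_accel) >= 1)
  if (!identical(as.numeric(sample_rate_hz), 1)) {
    stop("only a 1 Hz sample rate is supported", call. = FALSE)
  }
  start_time <- as_utc_time(start_time)
  structure(
    list(
      horse_id = as.character(horse_id),
      start_time = start_time,
      sample_rate_hz = 1,
      y_accel = as.numeric(y_accel),
      n_filled = as.integer(n_filled),
      missing_fraction = mean(is.na(y_accel)),
      high_missing = mean(is.na(y_accel)) > 0.10
    ),
    class = "accel_series"
  )
}

#' @exportS3Method
length.accel_series <- function(x) length(x$y_accel)

#' @exportS3Method base::print
print.accel_series <- function(x, ...) {
  cat(sprintf(
    "<accel_series> horse %s, %d samples @1 Hz from %s (%.1f%% missing%s)\n",
    x$horse_id, length(x), format(x$start_time, "%Y-%m-%d %H:%M:%S"),
    100 * x$missing_fraction,
    if (x$n_filled > 0) sprintf(", %d filled", x$n_filled) else ""
  ))
  invisible(x)
}

#' Per-sample timestamps of a series
#'
#' @param x An `accel_series` or `posture_series`.
#' @return `POSIXct` vector, one element per sample.
#' @export
series_timestamps <- function(x) {
  x$start_time + seq_len(length(x)) - 1
}

as_utc_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  }
  out <- as.POSIXct(x, tz = "UTC")
  if (any(is.na(out))) stop("unparseable timestamp: ", x[is.na(out)][1], call. = FALSE)
  out
}

#' Describe a logger CSV dialect
#'
#' The canonical dialect has a header row and columns `timestamp`
#' (ISO-8601 local time) and `y_acc_g` (decimal acceleration in g), with a
#' comma separator and `.` decimal mark. Real logger exports with other
#' column names, separators or decimal marks are mapped by overriding the
#' fields here (e.g. from the `io:` block of a YAML pipeline config).
#'
#' @param timestamp_col,accel_col Column names in the file.
#' @param sep Field separator.
#' @param dec Decimal mark.
#' @param time_formats Candidate `strptime` formats tried in order.
#' @return A `logger_dialect` list.
#' @export
logger_dialect <- function(timestamp_col = "timestamp", accel_col = "y_acc_g",
                           sep = ",", dec = ".",
                           time_formats = c("%Y-%m-%dT%H:%M:%S",
                                            "%Y-%m-%d %H:%M:%S")) {
  structure(list(timestamp_col = timestamp_col, accel_col = accel_col,
                 sep = sep, dec = dec, time_formats = time_formats),
            class = "logger_dialect")
}

parse_dialect_times <- function(x, dialect) {
  for (fmt in dialect$time_formats) {
    out <- as.POSIXct(strptime(x, fmt, tz = "UTC"))
    if (!anyNA(out)) return(out)
  }
  # report the first offending row under the most permissive format
  out <- as.POSIXct(strptime(x, dialect$time_formats[1], tz = "UTC"))
  bad <- which(is.na(out))[1]
  stop(sprintf("unparseable timestamp in row %d: '%s'", bad, x[bad]),
       call. = FALSE)
}

#' Read a logger CSV export onto a strict 1-second grid
#'
#' Rows are placed on a 1 s grid spanning the first to the last timestamp.
#' Grid seconds with no row become explicit missing samples; two rows on
#' the same second are an error, as are timestamps that go backwards.
#' A series missing more than 10% of its grid is flagged (not fatal) in
#' `$high_missing`.
#'
#' @param path Path to the CSV file.
#' @param dialect A [logger_dialect()].
#' @param horse_id Identifier recorded on the returned series.
#' @return An [accel_series()].
#' @export
read_logger_csv <- function(path, dialect = logger_dialect(),
                            horse_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           dec = dialect$dec, stringsAsFactors = FALSE,
                           check.names = FALSE)
  for (col in c(dialect$timestamp_col, dialect$accel_col)) {
    if (!col %in% names(raw)) {
      stop(sprintf("column '%s' not found in %s", col, path), call. = FALSE)
    }
  }
  times <- parse_dialect_times(raw[[dialect$timestamp_col]], dialect)
  vals <- as.numeric(raw[[dialect$accel_col]])
  if (is.unsorted(times, strictly = FALSE)) {
    bad <- which(diff(as.numeric(times)) < 0)[1] + 1L
    stop(sprintf("timestamps not monotone at row %d", bad), call. = FALSE)
  }
  sec <- round(as.numeric(times) - as.numeric(times[1]))
  if (anyDuplicated(sec)) {
    bad <- which(duplicated(sec))[1]
    stop(sprintf("colliding timestamps at row %d (%s)", bad,
                 format(times[bad], "%Y-%m-%d %H:%M:%S")), call. = FALSE)
  }
  n <- sec[length(sec)] + 1L
  y <- rep(NA_real_, n)
  y[sec + 1L] <- vals
  accel_series(y, start_time = times[1], horse_id = horse_id)
}

#' Write an acceleration series back to logger CSV
#'
#' Missing grid seconds are omitted from the file, so reading the result
#' back with [read_logger_csv()] reconstructs the identical series
#' (grid, gaps and values).
#'
#' @param series An [accel_series()].
#' @param path Output path.
#' @param dialect A [logger_dialect()].
#' @return `path`, invisibly.
#' @export
write_logger_csv <- function(series, path, dialect = logger_dialect()) {
  keep <- !is.na(series$y_accel)
  df <- data.frame(
    ts = format(series_timestamps(series)[keep], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    y = formatC(series$y_accel[keep], digits = 17, format = "g"),
    stringsAsFactors = FALSE
  )
  names(df) <- c(dialect$timestamp_col, dialect$accel_col)
  utils::write.table(df, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Fill short sensor dropouts by last observation carried forward
#'
#' Runs of at most `max_gap_s` consecutive missing samples are filled with
#' the last observed value; longer runs (and any leading gap, which has no
#' preceding observation) stay missing. Non-missing samples are never
#' altered. The count of filled samples is accumulated in `$n_filled`.
#'
#' @param series An [accel_series()].
#' @param max_gap_s Maximum gap length, in seconds, to fill.
#' @return The gap-filled [accel_series()].
#' @export
fill_short_gaps <- function(series, max_gap_s = 5) {
  stopifnot(inherits(series, "accel_series"), max_gap_s >= 0)
  y <- series$y_accel
  if (all(is.na(y))) stop("series is entirely missing", call. = FALSE)
  r <- rle(is.na(y))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  filled <- 0L
  for (k in which(r$values)) {
    if (r$lengths[k] <= max_gap_s && starts[k] > 1L) {
      y[starts[k]:ends[k]] <- y[starts[k] - 1L]
      filled <- filled + r$lengths[k]
    }
  }
  accel_series(y, series$start_time, series$horse_id,
               n_filled = series$n_filled + filled)
}
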