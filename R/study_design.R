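#' @keywords internal
condition_levels <- c("BOX", "ALONE", "PAIRS")
window_levels <- c("DAY", "NIGHT")

# the 6 orderings of the three daytime conditions, as a 6 x 3 matrix
condition_permutations <- function() {
  m <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
             c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  matrix(condition_levels[m], nrow = 6,
         dimnames = list(apply(matrix(condition_levels[m], nrow = 6), 1,
                               paste, collapse = "-"), NULL))
}

#' Generate a balanced crossover schedule
#'
#' Each horse passes through the three daytime conditions (box, paddock
#' alone, paddock in pairs) once per repetition, with a different
#' condition sequence in each of its repetitions. Across all
#' horse-by-repetition sequences the six possible orderings are used as
#' evenly as possible: each at least `floor(N/6)` times, with the
#' `N mod 6` surplus orderings drawn at random. For 10 horses and 2
#' repetitions this gives 20 sequences, every ordering used at least three
#' times and exactly two used four times.
#'
#' @param n_horses,n_reps Numbers of horses and repetitions per horse.
#'   `n_reps` cannot exceed 6 (a horse has only 6 distinct orderings).
#' @param seed Optional RNG seed making the allocation reproducible.
#' @param dates Optional vector of available calendar dates (the days the
#'   farm sets aside); defaults to synthetic consecutive dates. Each horse
#'   is assigned `3 * n_reps` distinct dates from this pool, in calendar
#'   order.
#' @param start_date First synthetic date when `dates` is not supplied.
#' @return A `crossover_schedule` data frame with columns `horse_id`,
#'   `repetition`, `position`, `condition`, `date`.
#' @export
generate_schedule <- function(n_horses, n_reps = 2, seed = NULL,
                              dates = NULL, start_date = as.Date("2022-03-01")) {
  stopifnot(n_horses >= 1, n_reps >= 1)
  if (n_reps > 6) {
    stop("infeasible: a horse has only 6 distinct condition sequences, ",
         "cannot run ", n_reps, " repetitions with all-different sequences",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  perms <- condition_permutations()
  n_seq <- n_horses * n_reps

  # multiset of sequence indices: floor(n_seq/6) of each, surplus at random
  counts <- rep(n_seq %/% 6L, 6L)
  r <- n_seq %% 6L
  if (r > 0) {
    extra <- sample.int(6L, r)
    counts[extra] <- counts[extra] + 1L
  }
  pool <- sample(rep.int(seq_len(6L), counts))

  # deal sequences to horses; repair until each horse's reps are distinct
  assign <- matrix(pool, nrow = n_horses, ncol = n_reps)
  for (attempt in seq_len(200L)) {
    dup_rows <- which(apply(assign, 1, anyDuplicated) > 0)
    if (length(dup_rows) == 0) break
    i <- dup_rows[1]
    d <- assign[i, which(duplicated(assign[i, ]))[1]]
    # swap the duplicate with a slot from a horse not holding d
    cands <- which(apply(assign, 1, function(x) !(d %in% x)))
    cands <- setdiff(cands, i)
    if (length(cands) == 0) {
      stop("infeasible sequence allocation for n_horses=", n_horses,
           ", n_reps=", n_reps, call. = FALSE)
    }
    j <- if (length(cands) == 1) cands else sample(cands, 1)
    # pick a column of j whose value is absent from row i
    jc <- which(!(assign[j, ] %in% assign[i, ]))
    jc <- if (length(jc) == 1) jc else sample(jc, 1)
    ic <- which(duplicated(assign[i, ]))[1]
    tmp <- assign[j, jc]
    assign[j, jc] <- assign[i, ic]
    assign[i, ic] <- tmp
  }
  if (any(apply(assign, 1, anyDuplicated) > 0)) {
    stop("could not allocate distinct per-horse sequences", call. = FALSE)
  }

  n_periods <- n_seq * 3L
  if (is.null(dates)) {
    # pool sized so roughly three horses share an observation date,
    # as when a farm schedules days off in small groups
    dates <- start_date + seq_len(max(3L * n_reps, ceiling(n_periods / 3))) - 1L
  }
  dates <- as.Date(dates)
  if (length(unique(dates)) < 3L * n_reps) {
    stop("need at least ", 3L * n_reps, " distinct available dates",
         call. = FALSE)
  }

  horse_ids <- sprintf("H%02d", seq_len(n_horses))
  rows <- vector("list", n_seq)
  k <- 0L
  for (i in seq_len(n_horses)) {
    horse_dates <- sort(sample(unique(dates), 3L * n_reps))
    for (rep_i in seq_len(n_reps)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        horse_id = horse_ids[i],
        repetition = rep_i,
        position = 1:3,
        condition = perms[assign[i, rep_i], ],
        date = horse_dates[(rep_i - 1L) * 3L + 1:3],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("crossover_schedule", "data.frame")
  out
}

schedule_sequences <- function(schedule) {
  key <- interaction(schedule$horse_id, schedule$repetition, drop = TRUE)
  ord <- order(schedule$horse_id, schedule$repetition, schedule$position)
  s <- schedule[ord, ]
  vapply(split(s$condition, key[ord]), paste, character(1), collapse = "-")
}

#' Validate a crossover schedule
#'
#' Report-only check of the design invariants: every condition exactly
#' once per horse-repetition, no horse repeating a sequence, and ordering
#' usage at least `floor(N/6)` across the schedule.
#'
#' @param schedule A `crossover_schedule` (or any data frame with the same
#'   columns).
#' @return A `schedule_validation` list: `ok`, a `checks` data frame
#'   (check, pass, detail) and the per-ordering usage table `perm_counts`.
#' @export
validate_schedule <- function(schedule) {
  checks <- list()
  add <- function(name, pass, detail) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }

  by_hr <- split(schedule$condition,
                 interaction(schedule$horse_id, schedule$repetition, drop = TRUE))
  complete <- all(vapply(by_hr, function(x) setequal(x, condition_levels) &&
                           length(x) == 3, logical(1)))
  add("each condition once per horse x repetition", complete,
      sprintf("%d horse-repetition blocks", length(by_hr)))

  seqs <- schedule_sequences(schedule)
  horse_of <- sub("\\..*$", "", names(seqs))
  distinct <- all(vapply(split(seqs, horse_of),
                         function(x) !anyDuplicated(x), logical(1)))
  add("repetition sequences differ within horse", distinct,
      if (distinct) "all horses" else paste(
        "identical sequences for",
        paste(names(which(vapply(split(seqs, horse_of), anyDuplicated,
                                 integer(1)) > 0)), collapse = ", ")))

  perm_names <- rownames(condition_permutations())
  perm_counts <- table(factor(seqs, levels = perm_names))
  n_seq <- length(seqs)
  min_required <- n_seq %/% 6L
  balanced <- min(perm_counts) >= min_required
  add("ordering usage >= floor(N/6)", balanced,
      sprintf("min count %d (required %d)", min(perm_counts), min_required))

  checks <- do.call(rbind, checks)
  structure(list(ok = all(checks$pass), checks = checks,
                 perm_counts = perm_counts,
                 n_periods = nrow(schedule)),
            class = "schedule_validation")
}

#' @exportS3Method base::print
print.schedule_validation <- function(x, ...) {
  cat(sprintf("<schedule_validation> %s (%d periods)\n",
              if (x$ok) "all checks pass" else "FAILURES", x$n_periods))
  for (i in seq_len(nrow(x$checks))) {
    cat(sprintf("  [%s] %s: %s\n",
                if (x$checks$pass[i]) "ok" else "FAIL",
                x$checks$check[i], x$checks$detail[i]))
  }
  cat("  ordering usage:",
      paste(sprintf("%s=%d", names(x$perm_counts), x$perm_counts),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a schedule CSV
#'
#' @param schedule A `crossover_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.table(schedule, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a schedule CSV
#'
#' @param path Path to a CSV written by [write_schedule_csv()].
#' @return A `crossover_schedule`.
#' @export
read_schedule_csv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
  out$date <- as.Date(out$date)
  class(out) <- c("crossover_schedule", "data.frame")
  out
}
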