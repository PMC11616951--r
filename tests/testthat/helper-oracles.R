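# Independent brute-force oracles and small constructors used across tests.
# Oracles deliberately re-derive results position by position, sharing no
# code with the package implementation.

T0 <- as.POSIXct("2022-03-01 08:00:00", tz = "UTC")

# build a posture_series from an integer vector (0 standing, 1 lying, NA)
make_posture <- function(states, start_time = T0, horse_id = "T") {
  acc <- ifelse(is.na(states), NA_real_, ifelse(states == 1L, 0, -1))
  threshold_classify(accel_series(acc, start_time, horse_id))
}

# per-position sliding-window majority vote: truncated centred window,
# missing votes excluded, ties to standing, no votes -> NA
oracle_majority <- function(s, w) {
  n <- length(s)
  h <- (w - 1) %/% 2
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    win <- s[max(1, i - h):min(n, i + h)]
    win <- win[!is.na(win)]
    if (length(win) == 0) next
    out[i] <- if (sum(win == 1L) > length(win) / 2) 1L else 0L
  }
  out
}

# maximal runs of identical non-missing values, as a data frame
oracle_runs <- function(s) {
  n <- length(s)
  out <- NULL
  i <- 1
  while (i <= n) {
    if (is.na(s[i])) {
      i <- i + 1
      next
    }
    j <- i
    while (j < n && !is.na(s[j + 1]) && s[j + 1] == s[i]) j <- j + 1
    out <- rbind(out, data.frame(value = s[i], start = i, len = j - i + 1))
    i <- j + 1
  }
  out
}

# random 0/1 posture vector with geometric-ish run structure
random_binary <- function(n, p_switch = 0.05) {
  s <- integer(n)
  s[1] <- sample(0:1, 1)
  flips <- stats::runif(n - 1) < p_switch
  for (i in seq_len(n - 1)) s[i + 1] <- if (flips[i]) 1L - s[i] else s[i]
  s
}

# metrics table with all six design cells over h horses and their dates
balanced_metrics <- function(cell_means, sigma2_horse = 0, sigma2_date = 0,
                             sigma2_resid = 0.25, n_horses = 10, n_reps = 2,
                             seed = NULL, outcome = "lying_h_per_h") {
  sched <- generate_schedule(n_horses, n_reps, seed = seed)
  simulate_experiment(
    sched,
    experiment_sim_params(cell_means = cell_means,
                          sigma2_horse = sigma2_horse,
                          sigma2_date = sigma2_date,
                          sigma2_resid = sigma2_resid, outcome = outcome),
    seed = if (is.null(seed)) NULL else seed + 1)
}
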