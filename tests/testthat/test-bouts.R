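# posture covering one full observation day: starts 08:00, 24 h
day_start <- as.POSIXct("2022-03-01 08:00:00", tz = "UTC")
D1 <- as.Date("2022-03-01")

# build a 24 h state vector from (state, seconds) run pairs
runs_to_states <- function(...) {
  runs <- list(...)
  out <- unlist(lapply(runs, function(r) rep(r[[1]], r[[2]])))
  stopifnot(length(out) == 86400)
  out
}

test_that("maximal runs become bouts that tile observed time", {
  b <- segment_bouts(make_posture(rep(1L, 100)))
  expect_equal(nrow(b), 1)
  expect_equal(b$state, "LYING")
  expect_equal(b$duration_s, 100)

  b2 <- segment_bouts(make_posture(c(rep(0L, 50), rep(1L, 30), rep(0L, 20))))
  expect_equal(b2$state, c("STANDING", "LYING", "STANDING"))
  expect_equal(b2$duration_s, c(50, 30, 20))
  expect_equal(sum(b2$duration_s), 100)
  expect_equal(as.numeric(b2$end - b2$start, units = "secs"), b2$duration_s)

  expect_equal(sum(segment_bouts(make_posture(rep(0L, 100)))$state == "LYING"), 0)
})

test_that("a dropout terminates the current bout", {
  s <- c(rep(1L, 40), rep(NA_integer_, 10), rep(1L, 50))
  b <- segment_bouts(make_posture(s))
  expect_equal(nrow(b), 2)
  expect_equal(b$state, c("LYING", "LYING"))
  expect_equal(b$duration_s, c(40, 50))
  expect_equal(nrow(segment_bouts(make_posture(rep(NA_integer_, 10)))), 0)
})

test_that("segmentation agrees with a brute-force run scan on random series", {
  set.seed(20260929)
  for (rep in 1:25) {
    s <- random_binary(500, runif(1, 0.01, 0.2))
    if (rep %% 2 == 0) s[sample(500, 30)] <- NA
    b <- segment_bouts(make_posture(s))
    o <- oracle_runs(s)
    expect_equal(nrow(b), nrow(o))
    expect_equal(b$duration_s, o$len)
    expect_equal(b$state, c("STANDING", "LYING")[o$value + 1])
  }
})

test_that("per-hour metrics follow the clip-and-normalize rule", {
  # three short lying bouts well inside the day window, rest standing
  s <- runs_to_states(
    list(0L, 3600),           # 08:00-09:00
    list(1L, 600), list(0L, 3600), list(1L, 600), list(0L, 3600),
    list(1L, 600),            # third bout ends 11:30:00
    list(0L, 86400 - 3600 - 3 * 600 - 2 * 3600))
  m <- period_metrics(make_posture(s, day_start), D1, "BOX")
  day <- m[m$window == "DAY", ]
  expect_equal(day$n_bouts_per_h, 3 / 7.5)
  expect_equal(day$observed_h, 7.5)
  expect_equal(day$lying_h_per_h, (1800 / 3600) / 7.5)
})

test_that("saturation and absence give the boundary values", {
  all_lying <- period_metrics(make_posture(rep(1L, 86400), day_start), D1, "BOX")
  night <- all_lying[all_lying$window == "NIGHT", ]
  expect_equal(night$lying_h_per_h, 1.0)
  expect_equal(night$n_bouts_per_h, 1 / 14.5)

  never <- period_metrics(make_posture(rep(0L, 86400), day_start), D1, "BOX")
  expect_equal(never$n_bouts_per_h, c(0, 0))
  expect_equal(never$lying_h_per_h, c(0, 0))
})

test_that("metrics error on zero observed time", {
  short <- make_posture(rep(0L, 600), day_start)  # ends before 08:30
  expect_error(compute_metrics(segment_bouts(short), day_window(), D1),
               "zero observed hours")
})

test_that("lying and standing seconds conserve the window length", {
  set.seed(5)
  for (rep in 1:5) {
    tr <- simulate_trace(trace_sim_params(noise_sd_g = 0), seed = rep,
                         start_time = day_start)
    states <- smooth_majority(threshold_classify(tr$series))
    b <- segment_bouts(states)
    for (w in list(day_window(), night_window())) {
      iv <- window_interval(w, D1)
      secs <- pmax(0, as.numeric(pmin(b$end, iv[2])) -
                        as.numeric(pmax(b$start, iv[1])))
      expect_equal(sum(secs), w$length_h * 3600)
    }
  }
})

test_that("adding a lying bout inside the window increases both metrics", {
  base <- runs_to_states(list(0L, 86400))
  with_bout <- base
  with_bout[7201:7800] <- 1L  # 10:00-10:10
  m0 <- period_metrics(make_posture(base, day_start), D1, "BOX")
  m1 <- period_metrics(make_posture(with_bout, day_start), D1, "BOX")
  d0 <- m0[m0$window == "DAY", ]
  d1 <- m1[m1$window == "DAY", ]
  expect_gt(d1$n_bouts_per_h, d0$n_bouts_per_h)
  expect_gt(d1$lying_h_per_h, d0$lying_h_per_h)
})

test_that("a bout straddling the window edge is clipped but counted", {
  # lying 15:50-16:10 straddles the day window's end
  s <- runs_to_states(list(0L, 28200), list(1L, 1200), list(0L, 57000))
  m <- period_metrics(make_posture(s, day_start), D1, "BOX")
  day <- m[m$window == "DAY", ]
  expect_equal(day$n_bouts_per_h, 1 / 7.5)
  expect_equal(day$lying_h_per_h, (600 / 3600) / 7.5)
})

test_that("the night window is attributed to the evening date", {
  iv <- window_interval(night_window(), D1)
  expect_equal(format(iv[1], "%Y-%m-%d %H:%M"), "2022-03-01 17:00")
  expect_equal(format(iv[2], "%Y-%m-%d %H:%M"), "2022-03-02 07:30")
  expect_equal(night_window()$length_h, 14.5)
  expect_equal(day_window()$length_h, 7.5)
})
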