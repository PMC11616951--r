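cm_dur <- default_cell_means("lying_h_per_h")

test_that("with no grouping variance the fixed effects match ordinary least squares", {
  d <- balanced_metrics(cm_dur, sigma2_horse = 0, sigma2_date = 0,
                        sigma2_resid = 0.3, seed = 20260929)
  fit <- fit_lmm(d, "lying_h_per_h", method = "ML", offset = 0)
  ols <- stats::lm(log(lying_h_per_h) ~ condition * window,
                   data = transform(d,
                     condition = factor(condition,
                                        c("BOX", "ALONE", "PAIRS")),
                     window = factor(window, c("DAY", "NIGHT"))))
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
})

test_that("pure fixed-effect data is reproduced exactly in the vanishing-noise limit", {
  d <- balanced_metrics(cm_dur, sigma2_horse = 0, sigma2_date = 0,
                        sigma2_resid = 1e-10, seed = 2)
  fit <- fit_lmm(d, "lying_h_per_h", offset = 0)
  cm_hat <- fitted_cell_means(fit)
  expect_equal(as.vector(cm_hat), unname(cm_dur), tolerance = 1e-4)
  expect_lt(fit$sigma2_horse, 1e-6)
  expect_lt(fit$sigma2_date, 1e-6)
})

test_that("refitting at the returned estimates reproduces the log-likelihood", {
  d <- balanced_metrics(cm_dur, 0.2, 0.1, 0.5, seed = 3)
  fit <- fit_lmm(d, "lying_h_per_h")
  refit <- suppressMessages(lme4::refit(fit$model,
                                        newresp = fit$model@resp$y))
  expect_equal(as.numeric(logLik(refit)), fit$loglik, tolerance = 1e-6)
})

test_that("the profiled optimum beats random parameter perturbations", {
  library(lme4)  # as.function.merMod needs lme4 attached
  d <- balanced_metrics(cm_dur, 0.2, 0.1, 0.5, seed = 4)
  fit <- fit_lmm(d, "lying_h_per_h")
  dev <- as.function(fit$model)  # profiled REML criterion in theta
  th <- fit$model@theta
  d_opt <- dev(th)
  set.seed(99)
  for (k in 1:100) {
    probe <- pmax(0, th + stats::rnorm(2, 0, 0.25))
    expect_gte(dev(probe), d_opt - 1e-8)
  }
})

test_that("contrast estimates are invariant to the fixed-effect coding", {
  d <- balanced_metrics(cm_dur, 0.2, 0.1, 0.5, seed = 5)
  fit_tr <- fit_lmm(d, "lying_h_per_h", method = "ML")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit_sum <- fit_lmm(d, "lying_h_per_h", method = "ML")
  options(old)
  expect_equal(marginal_condition_contrasts(fit_sum)$log_estimate,
               marginal_condition_contrasts(fit_tr)$log_estimate,
               tolerance = 1e-8)
  # the ML likelihood is coding-invariant (REML differs by log|det| of the
  # reparameterization)
  expect_equal(fit_sum$loglik, fit_tr$loglik, tolerance = 1e-6)
})

test_that("marginal contrasts equal a direct cell-mean average", {
  d <- balanced_metrics(cm_dur, 0.2, 0.1, 0.5, seed = 6)
  fit <- fit_lmm(d, "lying_h_per_h")
  cm <- fitted_cell_means(fit)
  got <- marginal_condition_contrasts(fit)
  manual <- c(
    alone_vs_box = mean(cm["ALONE", ]) - mean(cm["BOX", ]),
    pairs_vs_box = mean(cm["PAIRS", ]) - mean(cm["BOX", ]),
    night_vs_day = mean(cm[, "NIGHT"]) - mean(cm[, "DAY"])
  )
  expect_equal(got$log_estimate, unname(manual))
  expect_equal(got$factor, unname(exp(manual)))

  # identical cell means give unit factors
  d0 <- balanced_metrics(setNames(rep(log(0.2), 6), names(cm_dur)),
                         0, 0, 1e-10, seed = 7)
  f0 <- marginal_condition_contrasts(fit_lmm(d0, "lying_h_per_h", offset = 0))
  expect_equal(f0$factor, rep(1, 3), tolerance = 1e-4)

  # shifting night cells by log(2) doubles the night/day factor
  cm2 <- cm_dur
  cm2[grep("NIGHT", names(cm2))] <- cm2[grep("DAY", names(cm2))] + log(2)
  d2 <- balanced_metrics(cm2, 0, 0, 1e-10, seed = 8)
  f2 <- marginal_condition_contrasts(fit_lmm(d2, "lying_h_per_h", offset = 0))
  expect_equal(f2$factor[f2$name == "night_vs_day"], 2, tolerance = 1e-4)
})

test_that("marginal contrasts agree with emmeans on the same model", {
  library(emmeans)
  d <- balanced_metrics(cm_dur, 0.2, 0.1, 0.5, seed = 10)
  fit <- fit_lmm(d, "lying_h_per_h")
  em_w <- summary(emmeans::emmeans(fit$model, "window"))
  em_c <- summary(emmeans::emmeans(fit$model, "condition"))
  got <- marginal_condition_contrasts(fit)
  expect_equal(got$log_estimate[got$name == "night_vs_day"],
               em_w$emmean[em_w$window == "NIGHT"] -
                 em_w$emmean[em_w$window == "DAY"],
               tolerance = 1e-6)
  expect_equal(got$log_estimate[got$name == "alone_vs_box"],
               em_c$emmean[em_c$condition == "ALONE"] -
                 em_c$emmean[em_c$condition == "BOX"],
               tolerance = 1e-6)
})

test_that("degenerate inputs raise informative errors", {
  d <- balanced_metrics(cm_dur, 0.2, 0.1, 0.5, seed = 11)
  expect_error(fit_lmm(d[d$condition != "PAIRS", ], "lying_h_per_h"),
               "empty design cell: condition PAIRS")
  expect_error(fit_lmm(d[d$horse_id == "H01", ], "lying_h_per_h"),
               "at least 2 horses")
  dz <- d
  dz$lying_h_per_h[1] <- 0
  expect_error(fit_lmm(dz, "lying_h_per_h", offset = 0),
               "strictly positive")
})

test_that("the default offset is half the smallest observable nonzero value", {
  d <- balanced_metrics(cm_dur, 0.2, 0.1, 0.5, seed = 12)
  expect_equal(default_offset(d, "n_bouts_per_h"), 0)  # all positive
  d$n_bouts_per_h[3] <- 0
  expect_equal(default_offset(d, "n_bouts_per_h"), 0.5 / 14.5)
  d$lying_h_per_h[5] <- 0
  expect_equal(default_offset(d, "lying_h_per_h"), 0.5 / (3600 * 14.5))
})

test_that("the bootstrap p-value hits the formula floor when the effect dominates", {
  d <- balanced_metrics(cm_dur, 0.05, 0.05, 0.05, seed = 13)
  pt <- pb_test(d, "lying_h_per_h", "WINDOW", n_boot = 199, seed = 14)
  expect_equal(pt$p_value, 1 / 200)
  expect_equal(pt$n_boot_used, 199)
  expect_gt(pt$lrt, 0)
})

test_that("bootstrap tests are reproducible from the seed and p-values are in (0, 1]", {
  d <- balanced_metrics(cm_dur, 0.2, 0.1, 0.5, seed = 15)
  a <- pb_test(d, "lying_h_per_h", "CONDITION", n_boot = 99, seed = 16)
  b <- pb_test(d, "lying_h_per_h", "CONDITION", n_boot = 99, seed = 16)
  expect_identical(a, b)
  for (term in c("GLOBAL", "CONDITION", "WINDOW", "INTERACTION")) {
    p <- pb_test(d, "lying_h_per_h", term, n_boot = 49, seed = 17)$p_value
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("bootstrap intervals bracket the point estimate and degenerate cleanly", {
  d <- balanced_metrics(cm_dur, 0.2, 0.1, 0.5, seed = 18)
  ci <- pb_confint(d, "lying_h_per_h", n_boot = 99, seed = 19)
  expect_equal(ci$name, c("alone_vs_box", "pairs_vs_box", "night_vs_day"))
  expect_true(all(ci$ci_low <= ci$factor & ci$factor <= ci$ci_high))
  expect_true(all(ci$factor > 0))

  # an all-zero contrast vector is identically factor 1
  fit <- fit_lmm(d, "lying_h_per_h")
  z <- pb_confint(d, "lying_h_per_h",
                  contrasts = list(null = rep(0, length(fit$beta))),
                  n_boot = 49, seed = 20)
  expect_equal(z$factor, 1)
  expect_equal(c(z$ci_low, z$ci_high), c(1, 1))

  # near-noiseless data gives an interval collapsing onto the estimate
  d0 <- balanced_metrics(cm_dur, 0, 0, 1e-10, seed = 21)
  ci0 <- pb_confint(d0, "lying_h_per_h", contrasts = "night_vs_day",
                    n_boot = 49, seed = 22, offset = 0)
  expect_equal(ci0$ci_low, ci0$factor, tolerance = 1e-4)
  expect_equal(ci0$ci_high, ci0$factor, tolerance = 1e-4)
})

test_that("residuals are exposed for model checking", {
  d <- balanced_metrics(cm_dur, 0.2, 0.1, 0.5, seed = 23)
  fit <- fit_lmm(d, "lying_h_per_h")
  r <- residuals(fit)
  expect_length(r, nrow(d))
  expect_lt(abs(mean(r)), 0.2)
})
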