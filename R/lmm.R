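#' Default offset of the log transform
#'
#' Day windows can contain no lying at all (some horses skip recumbency on
#' some days), so the log transform needs an offset for zeros. The default
#' is half the smallest observable nonzero value of the outcome given the
#' observation windows in the data: half of one bout per observed hour for
#' the bout rate, half of one second of lying per observed hour for the
#' duration. When every outcome value is strictly positive the offset is
#' zero.
#'
#' @param data Metrics table with the outcome column and `observed_h`.
#' @param outcome `"n_bouts_per_h"` or `"lying_h_per_h"`.
#' @return A single non-negative number.
#' @export
default_offset <- function(data, outcome) {
  y <- data[[outcome]]
  if (all(y > 0)) return(0)
  granularity <- switch(outcome,
    n_bouts_per_h = 1 / data$observed_h,
    lying_h_per_h = (1 / 3600) / data$observed_h,
    stop("unknown outcome: ", outcome, call. = FALSE)
  )
  0.5 * min(granularity)
}

fixed_formulas <- list(
  full = ~ condition * window,
  additive = ~ condition + window,
  window_only = ~ window,
  condition_only = ~ condition,
  intercept_only = ~ 1
)

prep_model_frame <- function(data, outcome, offset) {
  need <- c("horse_id", "date", "condition", "window", outcome)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("metrics table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(
    horse_id = factor(data$horse_id),
    date = factor(as.character(data$date)),
    condition = factor(data$condition, levels = condition_levels),
    window = factor(data$window, levels = window_levels),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$condition) || anyNA(df$window)) {
    stop("condition/window labels outside ",
         paste(c(condition_levels, window_levels), collapse = "/"),
         call. = FALSE)
  }
  y <- data[[outcome]]
  if (offset == 0 && any(y <= 0)) {
    stop("offset 0 requires strictly positive outcomes", call. = FALSE)
  }
  df$.logy <- log(y + offset)
  if (nlevels(droplevels(df$horse_id)) < 2 || nlevels(droplevels(df$date)) < 2) {
    stop("need at least 2 horses and 2 calendar dates", call. = FALSE)
  }
  cells <- table(df$condition, df$window)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: condition %s x window %s",
                 condition_levels[empty[1]], window_levels[empty[2]]),
         call. = FALSE)
  }
  df
}

lmm_formula <- function(fixed = "full") {
  stats::as.formula(paste(".logy ~",
                          deparse(fixed_formulas[[fixed]][[2]]),
                          "+ (1 | horse_id) + (1 | date)"))
}

#' Fit the crossed random-intercepts model for one outcome
#'
#' Fits a Gaussian linear mixed model to the log-transformed outcome with
#' the full condition-by-window fixed-effect interaction and crossed
#' random intercepts for horse identity and calendar date, by REML or ML
#' profiled deviance (via [lme4::lmer()]; variance estimates are bounded
#' at zero).
#'
#' @param data Metrics table (`horse_id`, `date`, `condition`, `window`,
#'   outcome column).
#' @param outcome Outcome column name.
#' @param method `"REML"` (default) or `"ML"`.
#' @param offset Offset of the `log(y + c)` transform; `NULL` applies
#'   [default_offset()].
#' @param fixed Fixed-effect structure, one of `"full"`, `"additive"`,
#'   `"window_only"`, `"condition_only"`, `"intercept_only"` (reduced
#'   structures are used by the bootstrap tests).
#' @return An `equilying_fit`: fixed effects `beta` (log scale), variance
#'   components `sigma2_horse`, `sigma2_date`, `sigma2_resid`, `loglik`,
#'   `converged`, plus the underlying [lme4::lmerMod-class] object in
#'   `$model`.
#' @export
fit_lmm <- function(data, outcome = c("n_bouts_per_h", "lying_h_per_h"),
                    method = c("REML", "ML"), offset = NULL, fixed = "full") {
  outcome <- match.arg(outcome)
  method <- match.arg(method)
  stopifnot(fixed %in% names(fixed_formulas))
  if (is.null(offset)) offset <- default_offset(data, outcome)
  df <- prep_model_frame(data, outcome, offset)
  fit <- suppressMessages(
    lme4::lmer(lmm_formula(fixed), data = df, REML = method == "REML",
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- stats::setNames(vc$vcov, vc$grp)
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(
    beta = lme4::fixef(fit),
    vcov_beta = as.matrix(stats::vcov(fit)),
    sigma2_horse = unname(v[["horse_id"]]),
    sigma2_date = unname(v[["date"]]),
    sigma2_resid = unname(v[["Residual"]]),
    loglik = as.numeric(stats::logLik(fit)),
    converged = is.null(msgs) || length(msgs) == 0,
    contrasts = attr(stats::model.matrix(fit), "contrasts"),
    method = method, fixed = fixed,
    outcome = outcome, offset = offset,
    n_obs = nrow(df), model = fit
  ), class = "equilying_fit")
}

#' @exportS3Method base::print
print.equilying_fit <- function(x, ...) {
  cat(sprintf("<equilying_fit> %s on log(y + %.4g), %s, %d rows\n",
              x$outcome, x$offset, x$method, x$n_obs))
  cat(sprintf("  variances: horse %.4f, date %.4f, residual %.4f; logLik %.3f\n",
              x$sigma2_horse, x$sigma2_date, x$sigma2_resid, x$loglik))
  cm <- fitted_cell_means(x)
  cat("  cell means (log scale):\n")
  print(round(cm, 3))
  invisible(x)
}

#' @exportS3Method
residuals.equilying_fit <- function(object, ...) {
  stats::residuals(object$model, ...)
}

#' Fitted log-scale cell means of a full-interaction fit
#'
#' @param fit An `equilying_fit` with `fixed = "full"`.
#' @return 3 x 2 matrix (condition x window) of log-scale cell means.
#' @export
fitted_cell_means <- function(fit) {
  grid <- expand.grid(condition = factor(condition_levels,
                                         levels = condition_levels),
                      window = factor(window_levels, levels = window_levels))
  # use the coding the model was fitted under, not the session default
  carg <- fit$contrasts[intersect(names(fit$contrasts),
                                  all.vars(fixed_formulas[[fit$fixed]]))]
  X <- stats::model.matrix(fixed_formulas[[fit$fixed]], grid,
                           contrasts.arg = if (length(carg)) carg else NULL)
  X <- X[, names(fit$beta), drop = FALSE]
  matrix(as.vector(X %*% fit$beta), nrow = 3,
         dimnames = list(condition_levels, window_levels))
}

contrast_names <- c("alone_vs_box", "pairs_vs_box", "night_vs_day")

cell_contrast_weights <- function(name) {
  # weights on the 6 cells (rows BOX/ALONE/PAIRS x cols DAY/NIGHT),
  # equal-weight marginal averages over the other factor
  w <- matrix(0, 3, 2, dimnames = list(condition_levels, window_levels))
  switch(name,
    alone_vs_box = { w["ALONE", ] <- 1 / 2; w["BOX", ] <- -1 / 2 },
    pairs_vs_box = { w["PAIRS", ] <- 1 / 2; w["BOX", ] <- -1 / 2 },
    night_vs_day = { w[, "NIGHT"] <- 1 / 3; w[, "DAY"] <- -1 / 3 },
    stop("unknown contrast: ", name, call. = FALSE)
  )
  w
}

log_contrast <- function(fit, contrast) {
  cm <- fitted_cell_means(fit)
  if (is.character(contrast)) {
    sum(cell_contrast_weights(contrast) * cm)
  } else {
    stopifnot(length(contrast) == length(fit$beta))
    sum(contrast * fit$beta)
  }
}

#' Marginal condition and time-of-day contrasts as multiplicative factors
#'
#' Condition contrasts are differences of condition cell means averaged
#' with equal weight over day and night; the time-of-day contrast averages
#' equally over the three conditions. Exponentiation turns the log-scale
#' differences into fold changes of the (offset-shifted) outcome.
#'
#' @param fit An `equilying_fit` from [fit_lmm()].
#' @return Data frame with `name`, `log_estimate`, `factor`.
#' @export
marginal_condition_contrasts <- function(fit) {
  if (!fit$converged) warning("fit did not converge cleanly")
  est <- vapply(contrast_names, function(nm) log_contrast(fit, nm), numeric(1))
  data.frame(name = contrast_names, log_estimate = unname(est),
             factor = exp(unname(est)), stringsAsFactors = FALSE)
}

pb_refit_ml <- function(fit_full, fit_null, ystar) {
  f1 <- suppressMessages(lme4::refit(fit_full, newresp = ystar))
  f0 <- suppressMessages(lme4::refit(fit_null, newresp = ystar))
  2 * (as.numeric(stats::logLik(f1)) - as.numeric(stats::logLik(f0)))
}

pb_term_pair <- function(term) {
  switch(term,
    GLOBAL = c(full = "full", null = "window_only"),
    CONDITION = c(full = "additive", null = "window_only"),
    WINDOW = c(full = "additive", null = "condition_only"),
    INTERACTION = c(full = "full", null = "additive"),
    stop("unknown term: ", term, call. = FALSE)
  )
}

#' Parametric-bootstrap likelihood-ratio test of a model term
#'
#' Compares nested ML fits: the observed likelihood-ratio statistic is
#' referenced against its distribution under data simulated from the
#' fitted null model, each replicate refitting both models;
#' `p = (1 + #\{LRT* >= LRT_obs\}) / (B + 1)`. Term-to-model mapping:
#' `GLOBAL` tests the full condition-by-window structure against
#' time-of-day alone, `CONDITION` the additive condition effect,
#' `WINDOW` the additive time-of-day effect, `INTERACTION` the interaction
#' over the additive model.
#'
#' @param data Metrics table.
#' @param outcome Outcome column name.
#' @param term `"GLOBAL"`, `"CONDITION"`, `"WINDOW"` or `"INTERACTION"`.
#' @param n_boot Number of bootstrap replicates (>= 99 recommended).
#' @param seed RNG seed for the bootstrap.
#' @param offset Log-transform offset; `NULL` for [default_offset()].
#' @return List with `p_value`, `lrt`, `df` (difference in fixed-effect
#'   count), `n_boot_used`, `n_failed`, `term`.
#' @export
pb_test <- function(data, outcome, term, n_boot = 1000, seed = NULL,
                    offset = NULL) {
  stopifnot(n_boot >= 1)
  pair <- pb_term_pair(term)
  if (is.null(offset)) offset <- default_offset(data, outcome)
  fit_full <- fit_lmm(data, outcome, method = "ML", offset = offset,
                      fixed = pair[["full"]])
  fit_null <- fit_lmm(data, outcome, method = "ML", offset = offset,
                      fixed = pair[["null"]])
  lrt_obs <- max(0, 2 * (fit_full$loglik - fit_null$loglik))

  if (!is.null(seed)) set.seed(seed)
  ystars <- stats::simulate(fit_null$model, nsim = n_boot)
  lrt_star <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    lrt_star[b] <- tryCatch(
      pb_refit_ml(fit_full$model, fit_null$model, ystars[[b]]),
      error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(lrt_star))
  if (n_failed > 0.05 * n_boot) {
    stop(n_failed, " of ", n_boot, " bootstrap refits failed", call. = FALSE)
  }
  ok <- lrt_star[!is.na(lrt_star)]
  list(
    p_value = (1 + sum(ok >= lrt_obs)) / (length(ok) + 1),
    lrt = lrt_obs,
    df = length(fit_full$beta) - length(fit_null$beta),
    n_boot_used = length(ok),
    n_failed = n_failed,
    term = term
  )
}

#' Parametric-bootstrap confidence intervals on the factor scale
#'
#' Simulates responses from the fitted full model, refits each replicate,
#' and takes percentile intervals of the exponentiated contrasts. The
#' point estimate is the exponentiated contrast of the parent fit.
#'
#' @param data Metrics table.
#' @param outcome Outcome column name.
#' @param contrasts Character vector of named contrasts
#'   (`"alone_vs_box"`, `"pairs_vs_box"`, `"night_vs_day"`) and/or a list
#'   mixing names with numeric coefficient vectors on the fixed-effect
#'   scale.
#' @param n_boot Number of bootstrap replicates.
#' @param seed RNG seed.
#' @param level Confidence level.
#' @param offset Log-transform offset; `NULL` for [default_offset()].
#' @param method Fitting criterion of the parent model.
#' @return Data frame with one row per contrast: `name`, `log_estimate`,
#'   `factor`, `ci_low`, `ci_high`, `n_boot_used`, `n_failed`.
#' @export
pb_confint <- function(data, outcome, contrasts = contrast_names,
                       n_boot = 1000, seed = NULL, level = 0.95,
                       offset = NULL, method = "REML") {
  if (!is.list(contrasts)) contrasts <- as.list(contrasts)
  given <- names(contrasts)
  if (is.null(given)) given <- rep("", length(contrasts))
  nms <- vapply(seq_along(contrasts), function(i) {
    if (nzchar(given[i])) given[i]
    else if (is.character(contrasts[[i]])) contrasts[[i]]
    else paste0("contrast_", i)
  }, character(1))
  if (is.null(offset)) offset <- default_offset(data, outcome)
  fit <- fit_lmm(data, outcome, method = method, offset = offset)
  est <- vapply(contrasts, function(ct) log_contrast(fit, ct), numeric(1))

  if (!is.null(seed)) set.seed(seed)
  ystars <- stats::simulate(fit$model, nsim = n_boot)
  draws <- matrix(NA_real_, n_boot, length(contrasts))
  for (b in seq_len(n_boot)) {
    draws[b, ] <- tryCatch({
      refit_b <- suppressMessages(lme4::refit(fit$model, newresp = ystars[[b]]))
      shadow <- fit
      shadow$beta <- lme4::fixef(refit_b)
      vapply(contrasts, function(ct) log_contrast(shadow, ct), numeric(1))
    }, error = function(e) rep(NA_real_, length(contrasts)))
  }
  n_failed <- sum(is.na(draws[, 1]))
  if (n_failed > 0.05 * n_boot) {
    stop(n_failed, " of ", n_boot, " bootstrap refits failed", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  ci <- apply(exp(draws), 2, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)
  data.frame(
    name = nms,
    log_estimate = unname(est),
    factor = exp(unname(est)),
    ci_low = unname(ci[1, ]),
    ci_high = unname(ci[2, ]),
    n_boot_used = n_boot - n_failed,
    n_failed = n_failed,
    stringsAsFactors = FALSE
  )
}

#' Refit both outcome models on a deposited metrics table
#'
#' Convenience for reproducing published factor estimates from an archived
#' per-window metrics table (columns `horse_id`, `date`, `condition`,
#' `window`, `n_bouts_per_h`, `lying_h_per_h`, `observed_h`): fits both
#' outcomes, and returns the marginal contrasts with bootstrap intervals.
#'
#' @param path CSV file with the metrics table.
#' @param n_boot Bootstrap replicates for the intervals.
#' @param seed RNG seed.
#' @return Named list (per outcome) of contrast data frames.
#' @export
refit_published_models <- function(path, n_boot = 1000, seed = 1) {
  data <- utils::read.table(path, header = TRUE, sep = ",",
                            stringsAsFactors = FALSE)
  lapply(stats::setNames(nm = c("n_bouts_per_h", "lying_h_per_h")),
         function(oc) pb_confint(data, oc, n_boot = n_boot, seed = seed))
}
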