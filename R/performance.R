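# Discrimination, calibration and bootstrap optimism-corrected internal
# validation for logistic prognostic models.

#' Concordance index (c-index / AUC)
#'
#' Over all event/non-event pairs a concordant pair (event scored higher)
#' counts 1, a tied score 0.5, a discordant pair 0; the c-index is the
#' mean. Computed via the rank (Wilcoxon) identity, which handles ties
#' exactly.
#'
#' @param scores Predicted risks (any monotone score).
#' @param outcomes 0/1 indicators, both classes present.
#' @return The c-index in \[0, 1\].
#' @export
c_index <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  ok <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[ok]; outcomes <- outcomes[ok]
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confidence interval for the c-index
#'
#' Paired-placement (DeLong-type) asymptotic variance with a
#' normal-approximation interval, truncated to \[0, 1\].
#'
#' @param scores Predicted risks.
#' @param outcomes 0/1 indicators; at least 10 per class for the asymptotic
#'   variance to be trustworthy (warned otherwise).
#' @param level Coverage, default 0.95.
#' @return A list: `c`, `lower`, `upper`, `se`.
#' @export
c_index_ci <- function(scores, outcomes, level = 0.95) {
  ok <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[ok]; outcomes <- outcomes[ok]
  s1 <- scores[outcomes == 1]; s0 <- scores[outcomes == 0]
  n1 <- length(s1); n0 <- length(s0)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes required", call. = FALSE)
  if (n1 < 10L || n0 < 10L)
    warning("fewer than 10 subjects in a class; asymptotic CI unreliable",
            call. = FALSE)
  auc <- c_index(scores, outcomes)
  # placements: for each event, share of non-events it beats (ties half)
  v10 <- vapply(s1, function(a) (sum(a > s0) + 0.5 * sum(a == s0)) / n0, numeric(1))
  v01 <- vapply(s0, function(b) (sum(s1 > b) + 0.5 * sum(s1 == b)) / n1, numeric(1))
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(c = auc, lower = max(0, auc - z * se), upper = min(1, auc + z * se),
       se = se)
}

#' Calibration slope
#'
#' The slope from refitting the outcome on a model's linear predictor
#' (free intercept). On a model's own derivation data the maximum-likelihood
#' score equations force a slope of 1; on new data a slope below 1 signals
#' overfitting (predictions too extreme).
#'
#' @param linear_predictors Log-odds from the model under assessment.
#' @param outcomes 0/1 indicators, both classes present.
#' @return The slope coefficient.
#' @export
calibration_slope <- function(linear_predictors, outcomes) {
  ok <- !is.na(linear_predictors) & !is.na(outcomes)
  lp <- linear_predictors[ok]; y <- outcomes[ok]
  if (length(unique(y)) < 2L) stop("both outcome classes required", call. = FALSE)
  if (stats::sd(lp) == 0) stop("constant linear predictor", call. = FALSE)
  f <- logit_irls(cbind(1, lp), y)
  unname(f$coef[2])
}

#' Nagelkerke's R-squared
#'
#' Cox-Snell R-squared, `1 - exp(2 (LL0 - LL1) / n)`, rescaled by its
#' attainable maximum `1 - exp(2 LL0 / n)` so a perfect model scores 1.
#'
#' @param model A [fit_logistic()] model (needs `log_likelihood`,
#'   `null_log_likelihood`, `n`).
#' @return Nagelkerke R-squared in \[0, 1\].
#' @export
nagelkerke_r2 <- function(model) {
  n <- model$n
  if (is.null(n) || n == 0) stop("model has no recorded sample size", call. = FALSE)
  cs <- 1 - exp(2 * (model$null_log_likelihood - model$log_likelihood) / n)
  maxcs <- 1 - exp(2 * model$null_log_likelihood / n)
  if (maxcs <= 0) return(0)
  cs / maxcs
}

#' Bootstrap optimism-corrected internal validation
#'
#' Refits a fixed model composition on `b_validation` bootstrap resamples;
#' each bootstrap model is scored on its own resample and on the original
#' data, and the mean difference estimates the optimism of the apparent
#' performance. Corrected c-index = apparent c-index minus optimism; the
#' same scheme is applied to the calibration slope and Nagelkerke
#' R-squared. Non-converging replicates are excluded and counted; more
#' than 20 percent failures aborts the validation.
#'
#' @param x A [cohort()] complete on the used columns.
#' @param outcome Binary outcome name.
#' @param composition Character vector of predictor names (may be empty).
#' @param config An [analysis_config()] (uses `b_validation`).
#' @param seed Integer seed.
#' @return A list of class `performance_report`: `apparent_c`, `c_ci_low`,
#'   `c_ci_high`, `calibration_slope`, `r2_nagelkerke`, `optimism`,
#'   `corrected_c`, `optimism_slope`, `corrected_slope`, `optimism_r2`,
#'   `corrected_r2`, `failed_replicates`, `b`.
#' @export
validate_optimism <- function(x, outcome, composition,
                              config = analysis_config(), seed = 1L) {
  dat <- x$data[, c(outcome, composition), drop = FALSE]
  if (anyNA(dat)) stop("validation needs complete data", call. = FALSE)
  y <- dat[[outcome]]
  apparent <- fit_logistic(x, outcome, composition)
  lp_app <- apparent$linear_predictors
  p_app <- apparent$fitted
  ci <- c_index_ci(p_app, y)
  app_slope <- if (length(composition)) calibration_slope(lp_app, y) else 1
  app_r2 <- nagelkerke_r2(apparent)
  dm <- design_matrix(dat, x$spec, composition)
  n <- nrow(dat)
  set.seed(split_seeds(seed, 1L, tag = 404L))
  opt_c <- opt_slope <- opt_r2 <- numeric(0)
  failed <- 0L
  for (b in seq_len(config$b_validation)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (length(unique(yb)) < 2L) { failed <- failed + 1L; next }
    fb <- logit_irls(dm$X[idx, , drop = FALSE], yb)
    if (!fb$converged) { failed <- failed + 1L; next }
    cf <- fb$coef; cf[is.na(cf)] <- 0
    lp_boot <- drop(dm$X[idx, , drop = FALSE] %*% cf)
    lp_orig <- drop(dm$X %*% cf)
    c_boot <- c_index(lp_boot, yb)
    c_orig <- c_index(lp_orig, y)
    opt_c <- c(opt_c, c_boot - c_orig)
    if (length(composition)) {
      sl_boot <- 1  # ML identity on the bootstrap sample itself
      sl_orig <- tryCatch(calibration_slope(lp_orig, y), error = function(e) NA)
      if (!is.na(sl_orig)) opt_slope <- c(opt_slope, sl_boot - sl_orig)
    }
    ll0b <- null_loglik(yb)
    r2_boot <- local({
      cs <- 1 - exp(2 * (ll0b - fb$ll) / n); mx <- 1 - exp(2 * ll0b / n)
      if (mx <= 0) 0 else cs / mx
    })
    r2_orig <- local({  # bootstrap model scored on original data, coefficients fixed
      p0 <- pmin(pmax(stats::plogis(lp_orig), 1e-12), 1 - 1e-12)
      ll <- sum(y * log(p0) + (1 - y) * log1p(-p0))
      ll0 <- null_loglik(y)
      cs <- 1 - exp(2 * (ll0 - ll) / n); mx <- 1 - exp(2 * ll0 / n)
      if (mx <= 0) 0 else max(cs / mx, 0)
    })
    opt_r2 <- c(opt_r2, r2_boot - r2_orig)
  }
  if (failed > 0.2 * config$b_validation)
    stop(sprintf("validation failed: %d of %d replicates did not converge",
                 failed, config$b_validation), call. = FALSE)
  optimism <- if (length(opt_c)) mean(opt_c) else 0
  structure(list(apparent_c = ci$c, c_ci_low = ci$lower, c_ci_high = ci$upper,
                 calibration_slope = app_slope, r2_nagelkerke = app_r2,
                 optimism = optimism, corrected_c = ci$c - optimism,
                 optimism_slope = if (length(opt_slope)) mean(opt_slope) else 0,
                 corrected_slope = app_slope -
                   (if (length(opt_slope)) mean(opt_slope) else 0),
                 optimism_r2 = if (length(opt_r2)) mean(opt_r2) else 0,
                 corrected_r2 = app_r2 - (if (length(opt_r2)) mean(opt_r2) else 0),
                 failed_replicates = failed, b = config$b_validation),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report>\n")
  cat(sprintf("  apparent c  %.3f (%.3f, %.3f)\n", x$apparent_c, x$c_ci_low,
              x$c_ci_high))
  cat(sprintf("  slope       %.3f\n  R2 (Nagelkerke) %.3f\n",
              x$calibration_slope, x$r2_nagelkerke))
  cat(sprintf("  optimism    %.3f\n  corrected c %.3f\n", x$optimism,
              x$corrected_c))
  invisible(x)
}

#' Pooled performance across imputed data sets
#'
#' Runs [validate_optimism()] inside each completed data set and pools
#' each metric as the arithmetic mean over the m data sets; the c-index
#' confidence interval is pooled by Rubin's rules on the c scale (mean
#' within-variance plus (1 + 1/m) between-variance).
#'
#' @param imps An [impute()] result.
#' @param outcome Binary outcome name.
#' @param composition Predictor names.
#' @param config An [analysis_config()].
#' @param seed Integer seed.
#' @return A pooled `performance_report` with element `per_imputation`.
#' @export
mi_performance <- function(imps, outcome, composition,
                           config = analysis_config(), seed = 1L) {
  m <- imps$m
  seeds <- split_seeds(seed, m, tag = 505L)
  reports <- lapply(seq_len(m), function(i)
    validate_optimism(imps$completed[[i]], outcome, composition, config,
                      seed = seeds[i]))
  avg <- function(f) mean(vapply(reports, `[[`, numeric(1), f))
  cs <- vapply(reports, `[[`, numeric(1), "apparent_c")
  ses <- vapply(reports, function(r) (r$c_ci_high - r$c_ci_low) / (2 * stats::qnorm(0.975)),
                numeric(1))
  ubar <- mean(ses^2)
  b <- if (m > 1) stats::var(cs) else 0
  tot_se <- sqrt(ubar + (1 + 1 / m) * b)
  cbar <- mean(cs)
  z <- stats::qnorm(0.975)
  out <- list(apparent_c = cbar,
              c_ci_low = max(0, cbar - z * tot_se),
              c_ci_high = min(1, cbar + z * tot_se),
              calibration_slope = avg("calibration_slope"),
              r2_nagelkerke = avg("r2_nagelkerke"),
              optimism = avg("optimism"),
              corrected_c = cbar - avg("optimism"),
              optimism_slope = avg("optimism_slope"),
              corrected_slope = avg("calibration_slope") - avg("optimism_slope"),
              optimism_r2 = avg("optimism_r2"),
              corrected_r2 = avg("r2_nagelkerke") - avg("optimism_r2"),
              failed_replicates = sum(vapply(reports, `[[`, numeric(1),
                                             "failed_replicates")),
              b = config$b_validation, per_imputation = reports)
  class(out) <- "performance_report"
  out
}
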