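test_that("c-index handles perfect, random and tied scores", {
  expect_equal(c_index(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(c_index(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  # enumerated example: 3 concordant pairs + 1 tie of 4 pairs
  expect_equal(c_index(c(0.9, 0.4, 0.4, 0.1), c(1, 1, 0, 0)), 0.875)
  expect_error(c_index(c(0.1, 0.2), c(1, 1)), "both outcome classes")
})

test_that("c-index equals brute-force all-pairs concordance", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(20:300, 1)
    sc <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_identical(c_index(sc, y), c_index_bruteforce(sc, y))
  }
})

test_that("c-index agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  sc <- rnorm(200); y <- rbinom(200, 1, plogis(sc))
  expect_equal(c_index(sc, y),
               as.numeric(suppressMessages(pROC::auc(y, sc))),
               tolerance = 1e-12)
})

test_that("c-index interval contains the estimate and narrows with n", {
  set.seed(7)
  mk <- function(n) {
    y <- rep(c(0, 1), n / 2)
    s <- rnorm(n, mean = y * 0.74)  # binormal, AUC ~ 0.7
    c_index_ci(s, y)
  }
  small <- mk(100); big <- mk(1000)
  for (ci in list(small, big)) {
    expect_lte(ci$lower, ci$c)
    expect_gte(ci$upper, ci$c)
  }
  expect_lt(big$upper - big$lower, small$upper - small$lower)
})

test_that("the 95% interval has near-nominal coverage at known AUC", {
  # binormal model with separation delta: AUC = pnorm(delta / sqrt(2))
  delta <- sqrt(2) * qnorm(0.7)
  hits <- 0; reps <- 300
  set.seed(11)
  for (r in seq_len(reps)) {
    y <- rep(c(0, 1), each = 250)
    s <- rnorm(500, mean = y * delta)
    ci <- c_index_ci(s, y)
    if (ci$lower <= 0.7 && 0.7 <= ci$upper) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.92)
  expect_lte(hits / reps, 0.98)
})

test_that("calibration slope identities hold exactly", {
  co <- sim_cohort(300, c(0.8, 0.4), seed = 19)
  m <- fit_logistic(co, "y", c("x1", "x2"))
  lp <- m$linear_predictors
  y <- co$data$y
  expect_equal(calibration_slope(lp, y), 1.0, tolerance = 1e-6)
  expect_equal(calibration_slope(2 * lp, y), 0.5, tolerance = 1e-6)
  expect_error(calibration_slope(rep(1, 300), y), "constant")
})

test_that("overfitted models show slopes below 1 on fresh data", {
  slopes <- numeric(50)
  for (s in 1:50) {
    train <- sim_cohort(100, rep(0, 15), seed = 7000 + s)
    test <- sim_cohort(2000, rep(0, 15), seed = 8000 + s)
    m <- fit_logistic(train, "y", paste0("x", 1:15))
    lp_new <- predict(m, test, type = "link")
    slopes[s] <- tryCatch(calibration_slope(lp_new, test$data$y),
                          error = function(e) NA)
  }
  expect_lt(mean(slopes, na.rm = TRUE), 1)
})

test_that("Nagelkerke R2 matches hand-worked values and its bounds", {
  mk <- function(ll1, ll0, n) structure(
    list(log_likelihood = ll1, null_log_likelihood = ll0, n = n),
    class = "logistic_model")
  expect_equal(nagelkerke_r2(mk(-2.7726, -2.7726, 4)), 0)
  # n = 4 balanced null, LL1 = -1.3863: Cox-Snell 0.5, max 0.75
  r2 <- nagelkerke_r2(mk(-1.3863, -2.7726, 4))
  expect_equal(r2, 0.5 / 0.75, tolerance = 1e-4)
  expect_equal(nagelkerke_r2(mk(0, -2.7726, 4)), 1, tolerance = 1e-4)
  # monotone increasing in LL1 at fixed LL0 and n
  lls <- seq(-2.7, -0.1, by = 0.2)
  vals <- vapply(lls, function(l) nagelkerke_r2(mk(l, -2.7726, 4)), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("optimism validation satisfies its arithmetic invariants", {
  co <- sim_cohort(300, c(0.7, 0.4, 0, 0), seed = 23)
  cfg <- analysis_config(b_validation = 100)
  rep1 <- validate_optimism(co, "y", c("x1", "x2"), cfg, seed = 5)
  expect_equal(rep1$corrected_c, rep1$apparent_c - rep1$optimism)
  expect_lte(rep1$c_ci_low, rep1$apparent_c)
  expect_gte(rep1$c_ci_high, rep1$apparent_c)
  expect_equal(rep1$calibration_slope, 1, tolerance = 1e-6)
  # a selected/overfitted model has non-negative average optimism
  sel <- backward_eliminate(co, "y", paste0("x", 1:4), alpha = 0.5)
  rep2 <- validate_optimism(co, "y", sel$retained, cfg, seed = 6)
  expect_gte(rep2$optimism, 0)
  expect_lte(rep2$corrected_c, rep2$apparent_c)
})

test_that("the intercept-only model validates to c = 0.5 with zero optimism", {
  co <- sim_cohort(200, 0.5, seed = 27)
  rep0 <- validate_optimism(co, "y", character(),
                            analysis_config(b_validation = 50), seed = 2)
  expect_equal(rep0$apparent_c, 0.5)
  expect_equal(rep0$optimism, 0)
  expect_equal(rep0$corrected_c, 0.5)
})

test_that("MI performance pools to the single-data-set report when imputations are identical", {
  co <- sim_cohort(250, c(0.8, 0.3), seed = 33)  # complete data
  imps <- impute(co, m = 3, seed = 4)
  cfg <- analysis_config(b_validation = 60, m_imputations = 3)
  pooled <- mi_performance(imps, "y", c("x1", "x2"), cfg, seed = 9)
  expect_equal(pooled$corrected_c, pooled$apparent_c - pooled$optimism)
  # identical completed data sets: apparent metrics equal each per-imputation
  for (r in pooled$per_imputation) {
    expect_equal(r$apparent_c, pooled$apparent_c)
    expect_equal(r$calibration_slope, pooled$calibration_slope)
    expect_equal(r$r2_nagelkerke, pooled$r2_nagelkerke)
  }
})

test_that("pooled corrected c tracks independent-cohort performance", {
  g <- generate_cohort(recovery_preset(n = 600), seed = 91)
  imps <- impute(g$cohort, m = 5, seed = 92)
  comp <- paste0("x", 1:4)
  cfg <- analysis_config(b_validation = 100)
  pooled <- mi_performance(imps, "persistent", comp, cfg, seed = 93)
  # holdout oracle: the same composition fitted on one completed set,
  # evaluated on a fresh large cohort from the same generator
  holdout <- generate_cohort(recovery_preset(n = 5000, mar_rate = 0), seed = 94)
  hold_cc <- complete_cases(holdout$cohort)
  m <- fit_logistic(imps$completed[[1]], "persistent", comp)
  c_ext <- c_index(predict(m, hold_cc), hold_cc$data$persistent)
  expect_lt(abs(pooled$corrected_c - c_ext), 0.05)
})
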