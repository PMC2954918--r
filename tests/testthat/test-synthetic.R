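test_that("generator specs validate correlation, rates and coefficient names", {
  preds <- list(list(name = "a", measurement = "continuous", mean = 0, sd = 1),
                list(name = "b", measurement = "binary", prevalence = 0.3))
  expect_error(generator_spec(10, preds, true_coefficients = c(zz = 1)),
               "unknown predictor")
  expect_error(generator_spec(10, preds,
                              missingness = list(mcar = c(a = 1.2))),
               "rates")
  bad_R <- matrix(c(1, 2, 2, 1), 2)
  gs <- generator_spec(100, preds, correlation = bad_R)
  expect_error(generate_cohort(gs), "positive semi-definite")
})

test_that("a fixed seed yields a bit-identical cohort", {
  gs <- recovery_preset(n = 200)
  a <- generate_cohort(gs, seed = 5)
  b <- generate_cohort(gs, seed = 5)
  expect_identical(a$cohort$data, b$cohort$data)
  expect_identical(a$truth, b$truth)
  d <- generate_cohort(gs, seed = 6)
  expect_false(identical(a$cohort$data, d$cohort$data))
})

test_that("zero missingness rates produce a complete table with the implied prevalence", {
  gs <- recovery_preset(n = 2000, mar_rate = 0)
  gs$missingness <- list()
  prevs <- vapply(1:20, function(s) {
    g <- generate_cohort(gs, seed = s)
    expect_false(anyNA(g$cohort$data))
    mean(g$cohort$data$persistent)
  }, numeric(1))
  # oracle: large-sample Monte Carlo of the same logistic marginal
  set.seed(999)
  p <- length(gs$predictors)
  R <- matrix(0.15, p, p); diag(R) <- 1; R[1, 5] <- R[5, 1] <- 0.45
  Z <- MASS::mvrnorm(2e5, rep(0, p), R)
  prev_oracle <- mean(plogis(drop(Z[, 1:4] %*% rep(0.7, 4))))
  mcse <- sd(prevs) / sqrt(length(prevs))
  expect_lt(abs(mean(prevs) - prev_oracle), 3 * mcse + 0.005)
})

test_that("MCAR holes appear at the requested rate", {
  preds <- list(list(name = "a", measurement = "continuous", mean = 0, sd = 1),
                list(name = "b", measurement = "continuous", mean = 0, sd = 1))
  gs <- generator_spec(10000, preds, missingness = list(mcar = c(a = 0.1)))
  g <- generate_cohort(gs, seed = 3)
  expect_lt(abs(mean(is.na(g$cohort$data$a)) - 0.100), 0.01)
  expect_equal(sum(is.na(g$cohort$data$b)), 0L)
})

test_that("MAR missingness driven by a covariate selects the expected subjects", {
  # outcome missingness driven by young age: missing-outcome subjects are
  # younger on average
  preds <- list(list(name = "age", measurement = "continuous",
                     mean = 50, sd = 14),
                list(name = "z", measurement = "continuous", mean = 0, sd = 1))
  gs <- generator_spec(4000, preds, true_coefficients = c(z = 0.5),
                       missingness = list(mar = list(persistent = list(
                         rate = 0.12, logodds = c(age = -0.7)))))
  g <- generate_cohort(gs, seed = 17)
  miss <- is.na(g$cohort$data$persistent)
  expect_gt(mean(miss), 0.08); expect_lt(mean(miss), 0.16)
  expect_lt(mean(g$cohort$data$age[miss]), mean(g$cohort$data$age[!miss]))
})

test_that("the shoulder-cohort preset reproduces the published shape", {
  ages <- excl <- numeric(20)
  for (s in 1:20) {
    g <- generate_cohort(dss_preset(), seed = s)
    expect_equal(nrow(g$cohort$data), 587L)
    ages[s] <- mean(g$cohort$data$age, na.rm = TRUE)
    excl[s] <- attr(complete_cases(g$cohort), "excluded_fraction")
  }
  expect_lt(abs(mean(ages) - 51), 2)
  expect_gt(mean(excl), 0.20)
  expect_lt(mean(excl), 0.30)
  # outcome missingness near 12-13%, predictors within 0-9.2%
  g <- generate_cohort(dss_preset(), seed = 42)
  miss_frac <- colMeans(missing_mask(g$cohort))
  expect_gt(miss_frac["persistent"], 0.09)
  expect_lt(miss_frac["persistent"], 0.16)
  expect_true(all(miss_frac[names(miss_frac) != "persistent"] <= 0.095))
})

test_that("CCA is unbiased under MCAR but biased under outcome-linked MAR", {
  # MCAR variant: CCA and MI agree within Monte-Carlo error;
  # MAR variant: CCA's x1 coefficient is further from truth than MI's
  reps <- 30
  bias <- matrix(NA_real_, reps, 4,
                 dimnames = list(NULL, c("cca_mcar", "mi_mcar",
                                         "cca_mar", "mi_mar")))
  comp <- paste0("x", 1:4)
  for (r in seq_len(reps)) {
    gs_mar <- recovery_preset(n = 500)
    g <- generate_cohort(gs_mar, seed = 4000 + r)
    cc <- complete_cases(g$cohort, c("persistent", comp))
    bias[r, "cca_mar"] <-
      fit_logistic(cc, "persistent", comp)$coefficients[["x1"]] - 0.7
    imps <- impute(g$cohort, m = 5, seed = 4500 + r)
    pooled <- pool_rubin(lapply(imps$completed, fit_logistic,
                                outcome = "persistent", predictors = comp))
    bias[r, "mi_mar"] <- pooled$estimate[pooled$term == "x1"] - 0.7

    gs_mcar <- recovery_preset(n = 500)
    gs_mcar$missingness <- list(mcar = c(x1 = 0.10, x2 = 0.08, x3 = 0.06))
    g2 <- generate_cohort(gs_mcar, seed = 5000 + r)
    cc2 <- complete_cases(g2$cohort, c("persistent", comp))
    bias[r, "cca_mcar"] <-
      fit_logistic(cc2, "persistent", comp)$coefficients[["x1"]] - 0.7
    imps2 <- impute(g2$cohort, m = 5, seed = 5500 + r)
    pooled2 <- pool_rubin(lapply(imps2$completed, fit_logistic,
                                 outcome = "persistent", predictors = comp))
    bias[r, "mi_mcar"] <- pooled2$estimate[pooled2$term == "x1"] - 0.7
  }
  mb <- colMeans(bias)
  # under MCAR both are consistent: difference within MC error
  se_diff <- sd(bias[, "cca_mcar"] - bias[, "mi_mcar"]) / sqrt(reps)
  expect_lt(abs(mb["cca_mcar"] - mb["mi_mcar"]), 3 * se_diff + 0.02)
  # under MAR the complete-case bias dominates
  expect_gt(abs(mb["cca_mar"]), abs(mb["mi_mar"]))
})
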