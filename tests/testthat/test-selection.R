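test_that("fit_logistic matches closed forms on degenerate designs", {
  # intercept-only: logit of the event fraction, LL equals null LL
  dat <- data.frame(y = c(1, 1, 1, 0))
  co <- cohort(dat, cohort_spec(var_spec("y", "outcome_raw", "binary")))
  m <- fit_logistic(co, "y")
  expect_equal(m$intercept, qlogis(0.75), tolerance = 1e-6)
  expect_equal(m$log_likelihood, m$null_log_likelihood, tolerance = 1e-8)

  # balanced 2x2 symmetry: both coefficients zero
  dat2 <- data.frame(x1 = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  sp2 <- cohort_spec(var_spec("x1", measurement = "binary", clinical_priority = 1),
                     var_spec("y", "outcome_raw", "binary"))
  m2 <- fit_logistic(cohort(dat2, sp2), "y", "x1")
  expect_equal(m2$intercept, 0, tolerance = 1e-6)
  expect_equal(unname(m2$coefficients["x1"]), 0, tolerance = 1e-6)
})

test_that("fit_logistic agrees with stats::glm on a mixed-type design", {
  co <- toy_cohort(n = 150, seed = 31)
  m <- fit_logistic(co, "y", c("age", "smoker", "grade"))
  ref <- glm(y ~ age + smoker + factor(grade), binomial(), data = co$data)
  expect_equal(m$intercept, unname(coef(ref)[1]), tolerance = 1e-5)
  expect_equal(unname(m$coefficients),
               unname(coef(ref)[-1]), tolerance = 1e-5)
  expect_equal(m$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-7)
  ses <- sqrt(diag(vcov(ref)))
  expect_equal(unname(c(m$intercept_se, m$se)), unname(ses), tolerance = 1e-4)
})

test_that("fit_logistic recovers a known effect within 3 standard errors", {
  co <- sim_cohort(500, 0.7, seed = 17)
  m <- fit_logistic(co, "y", "x1")
  expect_lt(abs(m$coefficients[["x1"]] - 0.7), 3 * m$se[["x1"]])
})

test_that("backward elimination honours its alpha limits", {
  co <- sim_cohort(200, c(0, 0, 0), seed = 23)
  # alpha = 1 (practically): full starting model retained
  full <- backward_eliminate(co, "y", c("x1", "x2", "x3"), alpha = 0.999999)
  expect_setequal(full$retained, c("x1", "x2", "x3"))
  # alpha -> 0: everything noise is removed
  none <- backward_eliminate(co, "y", c("x1", "x2", "x3"), alpha = 1e-12)
  expect_length(none$retained, 0L)
  expect_equal(nrow(none$trace), 3L)
  # a strong predictor survives
  co2 <- sim_cohort(500, 1.0, seed = 29)
  keep <- backward_eliminate(co2, "y", "x1", alpha = 0.157)
  expect_equal(keep$retained, "x1")
})

test_that("retained sets are monotone in alpha along the elimination path", {
  co <- sim_cohort(300, c(0.8, 0.3, 0, 0), seed = 41)
  alphas <- c(0.5, 0.157, 0.05, 0.001)
  sets <- lapply(alphas, function(a)
    backward_eliminate(co, "y", paste0("x", 1:4), alpha = a)$retained)
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("removal sequence matches an independently coded greedy LRT oracle", {
  # oracle: greedy backward elimination via stats::drop1 on glm fits
  oracle_backward <- function(dat, start, alpha) {
    removed <- character()
    active <- start
    while (length(active)) {
      f <- glm(reformulate(active, "y"), binomial(), data = dat)
      dr <- drop1(f, test = "LRT")
      ps <- dr[["Pr(>Chi)"]][-1]
      names(ps) <- rownames(dr)[-1]
      ps <- ps[active]  # canonical order; which.max takes the first maximum
      if (max(ps) <= alpha) break
      worst <- max(ps)
      cand <- names(ps)[ps == worst]
      drop_var <- cand[length(cand)]
      removed <- c(removed, drop_var)
      active <- setdiff(active, drop_var)
    }
    list(removed = removed, retained = active)
  }
  for (s in 1:25) {
    p <- sample(3:4, 1)
    co <- sim_cohort(100, rnorm(p, 0, 0.5), seed = 1000 + s)
    start <- paste0("x", seq_len(p))
    mine <- backward_eliminate(co, "y", start, alpha = 0.157)
    theirs <- oracle_backward(co$data, start, 0.157)
    expect_identical(mine$trace$removed, theirs$removed)
    expect_setequal(mine$retained, theirs$retained)
  }
})

test_that("drop-one LRT statistics along the path are non-negative", {
  co <- sim_cohort(200, c(0.5, 0, 0), seed = 55)
  res <- backward_eliminate(co, "y", c("x1", "x2", "x3"), alpha = 0.5)
  expect_true(all(res$trace$p_value >= 0 & res$trace$p_value <= 1))
  m_full <- fit_logistic(co, "y", c("x1", "x2", "x3"))
  m_red <- fit_logistic(co, "y", c("x1", "x2"))
  expect_gte(2 * (m_full$log_likelihood - m_red$log_likelihood), -1e-8)
})

test_that("inclusion-fraction qualification uses the >= 40% rule", {
  # five final models; a predictor in exactly 2 qualifies, in 1 does not
  finals <- list(c("a", "b"), c("a", "c"), "a", "a", "a")
  tab <- stabmi:::inclusion_table(finals, c("a", "b", "c"))
  expect_equal(tab$fraction[tab$predictor == "a"], 1.0)
  expect_equal(tab$fraction[tab$predictor == "b"], 0.2)
  expect_equal(tab$fraction[tab$predictor == "c"], 0.2)
  finals2 <- list(c("a", "b"), c("a", "b"), "a", "a", "a")
  tab2 <- stabmi:::inclusion_table(finals2, c("a", "b"))
  expect_equal(tab2$fraction[tab2$predictor == "b"], 0.4)
  expect_true(tab2$fraction[tab2$predictor == "b"] >= 0.4)
})

test_that("mi_select with m = 1 degenerates to backward elimination", {
  co <- sim_cohort(300, c(0.9, 0.6, 0, 0), seed = 61)
  imps <- impute(co, m = 1, seed = 5)  # complete data: identity copies
  cfg <- analysis_config(m_imputations = 1)
  sel <- mi_select(imps, "y", paste0("x", 1:4), cfg)
  scr <- univariable_screen(co, "y", paste0("x", 1:4), cfg$alpha_univariable)
  bk <- backward_eliminate(co, "y", scr$retained, cfg$alpha_backward)
  expect_setequal(sel$confirmed, bk$retained)
})

test_that("mi_select finds true structure through imputed data", {
  g <- generate_cohort(recovery_preset(n = 600), seed = 77)
  imps <- impute(g$cohort, m = 5, seed = 78)
  sel <- mi_select(imps, "persistent", paste0("x", 1:12))
  expect_true(all(paste0("x", 1:4) %in% sel$confirmed))
  # pooled coefficients agree in sign with the generating truth
  pooled <- pool_rubin(sel$models)
  for (v in paste0("x", 1:4))
    expect_gt(pooled$estimate[pooled$term == v], 0)
})

test_that("Rubin's rules pool estimates and variances correctly", {
  co <- sim_cohort(200, 0.5, seed = 71)
  m <- fit_logistic(co, "y", "x1")
  # m identical models: pooled = common estimate, zero between-variance
  pooled_id <- pool_rubin(list(m, m, m))
  expect_equal(pooled_id$estimate[2], unname(m$coefficients["x1"]))
  expect_equal(pooled_id$between_var, c(0, 0))
  expect_equal(pooled_id$total_var, pooled_id$within_var)
  # hand-worked two-imputation case: estimates 0.4/0.6, within-var 0.01
  m1 <- m; m2 <- m
  m1$coefficients["x1"] <- 0.4; m2$coefficients["x1"] <- 0.6
  m1$se["x1"] <- 0.1; m2$se["x1"] <- 0.1
  out <- pool_rubin(list(m1, m2))
  expect_equal(out$estimate[out$term == "x1"], 0.5)
  expect_equal(out$total_var[out$term == "x1"], 0.01 + 1.5 * 0.02,
               tolerance = 1e-12)
  # mismatched compositions refuse to pool
  m3 <- fit_logistic(co, "y")
  expect_error(pool_rubin(list(m, m3)), "composition")
})
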