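# Fixtures built in code: small cohorts with known structure.

# Continuous-predictor cohort with logistic outcome y ~ intercept + X beta.
sim_cohort <- function(n, beta, intercept = 0, seed = 1, rho = 0,
                       outcome = "y") {
  set.seed(seed)
  p <- length(beta)
  X <- matrix(rnorm(n * p), n, p)
  if (rho > 0) {
    R <- matrix(rho, p, p); diag(R) <- 1
    X <- X %*% chol(R)
  }
  colnames(X) <- paste0("x", seq_len(p))
  y <- rbinom(n, 1, plogis(intercept + drop(X %*% beta)))
  dat <- cbind(as.data.frame(X), setNames(data.frame(y), outcome))
  specs <- c(lapply(seq_len(p), function(j)
    var_spec(paste0("x", j), "candidate", "continuous", clinical_priority = j)),
    list(var_spec(outcome, "outcome_raw", "binary")))
  cohort(dat, do.call(cohort_spec, specs))
}

# Tiny fixed-layout cohort for IO tests: 2 continuous, 1 binary, 1
# categorical, binary outcome.
toy_spec <- function() {
  cohort_spec(
    var_spec("age", "candidate", "continuous", clinical_priority = 1),
    var_spec("score", "candidate", "continuous", clinical_priority = 2),
    var_spec("smoker", "candidate", "binary", clinical_priority = 3),
    var_spec("grade", "candidate", "categorical",
             levels = c("low", "mid", "high"), clinical_priority = 4),
    var_spec("y", "outcome_raw", "binary"))
}

toy_cohort <- function(n = 50, seed = 1, miss = 0) {
  set.seed(seed)
  dat <- data.frame(age = rnorm(n, 50, 10),
                    score = rnorm(n, 0, 1),
                    smoker = rbinom(n, 1, 0.3),
                    grade = sample(1:3, n, replace = TRUE),
                    y = rbinom(n, 1, 0.5))
  if (miss > 0)
    for (v in c("age", "score", "grade"))
      dat[[v]][runif(n) < miss] <- NA
  cohort(dat, toy_spec())
}

# Brute-force c-index oracle: loop over all event/non-event pairs.
c_index_bruteforce <- function(scores, outcomes) {
  s1 <- scores[outcomes == 1]
  s0 <- scores[outcomes == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s1) * length(s0))
}
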