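# Synthetic cohort generator with known truth.
#
# Mixed-type predictors are generated through a latent-normal copula:
# correlated standard normals are thresholded into binary / categorical
# variables or rescaled into continuous scores. The binary outcome is drawn
# from a logistic model on the generated predictors, and missingness is
# then punched in under MCAR or MAR. Because the generating coefficients
# are recorded, recovery of the true predictor set and coefficient bias are
# directly testable.

#' Describe a synthetic cohort
#'
#' @param n Number of subjects.
#' @param predictors List of predictor descriptions; each element a list
#'   with `name`, `measurement` (`"continuous"`, `"binary"`,
#'   `"categorical"`) and parameters: `mean`/`sd` (continuous),
#'   `prevalence` (binary), `probs` + `levels` (categorical).
#' @param correlation `NULL` (independence), a scalar exchangeable latent
#'   correlation, or a full positive semi-definite matrix on the latent
#'   scale.
#' @param true_coefficients Named log-odds vector; unnamed predictors are
#'   noise (coefficient 0). Coefficients act on the standardized latent
#'   score for continuous variables, the 0/1 value for binary, and
#'   `code - 1` for categorical (a per-step trend).
#' @param intercept Log-odds intercept of the outcome model.
#' @param missingness List with optional elements `mcar` (named rate
#'   vector) and `mar` (named list; each element a list with `rate` and
#'   `logodds`, a named vector of log-odds on standardized observed
#'   drivers — `".outcome"` refers to the outcome, and a name like
#'   `"x5:.outcome"` denotes their product). MAR drivers must themselves
#'   be fully observed.
#' @param outcome_name Name for the generated binary outcome column.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n, predictors, correlation = NULL,
                           true_coefficients = numeric(), intercept = 0,
                           missingness = list(), outcome_name = "persistent") {
  nm <- vapply(predictors, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate predictor names", call. = FALSE)
  rates <- c(unlist(missingness$mcar),
             vapply(missingness$mar %||% list(), `[[`, numeric(1), "rate"))
  if (length(rates) && any(rates < 0 | rates >= 1))
    stop("missingness rates must lie in [0, 1)", call. = FALSE)
  bad <- setdiff(names(true_coefficients), nm)
  if (length(bad))
    stop("true_coefficients name unknown predictor(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(n = as.integer(n), predictors = predictors,
                 correlation = correlation,
                 true_coefficients = true_coefficients,
                 intercept = intercept, missingness = missingness,
                 outcome_name = outcome_name),
            class = "generator_spec")
}

latent_correlation <- function(gspec) {
  p <- length(gspec$predictors)
  R <- gspec$correlation
  if (is.null(R)) return(diag(p))
  if (is.matrix(R)) {
    if (nrow(R) != p || ncol(R) != p)
      stop("correlation matrix must be ", p, "x", p, call. = FALSE)
  } else {
    R <- matrix(R, p, p); diag(R) <- 1
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("latent correlation matrix is not positive semi-definite", call. = FALSE)
  R
}

#' Generate a synthetic cohort with known truth
#'
#' @param gspec A [generator_spec()].
#' @param seed Integer seed; a fixed seed yields a bit-identical cohort.
#' @return A list: `cohort` (a [cohort()] including the outcome column) and
#'   `truth` (generating `intercept`, `coefficients`, the complete
#'   pre-missingness data, linear predictor and event probabilities).
#' @export
generate_cohort <- function(gspec, seed = 1L) {
  set.seed(as.integer(seed))
  n <- gspec$n
  preds <- gspec$predictors
  p <- length(preds)
  R <- latent_correlation(gspec)
  Z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = R)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = n)
  nm <- vapply(preds, `[[`, character(1), "name")
  colnames(Z) <- nm
  X <- as.data.frame(matrix(NA_real_, n, p, dimnames = list(NULL, nm)))
  term <- matrix(0, n, p, dimnames = list(NULL, nm))
  spec_rows <- vector("list", p)
  for (j in seq_len(p)) {
    pr <- preds[[j]]
    z <- Z[, j]
    if (pr$measurement == "continuous") {
      X[[j]] <- pr$mean + pr$sd * z
      term[, j] <- z
      spec_rows[[j]] <- var_spec(pr$name, "candidate", "continuous",
                                 clinical_priority = j)
    } else if (pr$measurement == "binary") {
      X[[j]] <- as.numeric(z > stats::qnorm(1 - pr$prevalence))
      term[, j] <- X[[j]]
      spec_rows[[j]] <- var_spec(pr$name, "candidate", "binary",
                                 clinical_priority = j)
    } else {
      probs <- pr$probs / sum(pr$probs)
      cuts <- stats::qnorm(cumsum(probs)[-length(probs)])
      X[[j]] <- as.numeric(findInterval(z, cuts) + 1)
      term[, j] <- X[[j]] - 1
      spec_rows[[j]] <- var_spec(pr$name, "candidate", "categorical",
                                 levels = pr$levels %||%
                                   paste0("L", seq_along(probs)),
                                 clinical_priority = j)
    }
  }
  beta <- stats::setNames(rep(0, p), nm)
  beta[names(gspec$true_coefficients)] <- gspec$true_coefficients
  lp <- gspec$intercept + drop(term %*% beta)
  prob <- stats::plogis(lp)
  y <- stats::rbinom(n, 1L, prob)
  complete <- cbind(X, stats::setNames(data.frame(y), gspec$outcome_name))
  out <- complete
  # MCAR holes
  for (v in names(gspec$missingness$mcar %||% numeric())) {
    r <- gspec$missingness$mcar[[v]]
    out[[v]][stats::runif(n) < r] <- NA
  }
  # MAR holes: logit(miss) = a + sum(w_k * driver_k), a calibrated to rate
  for (v in names(gspec$missingness$mar %||% list())) {
    mm <- gspec$missingness$mar[[v]]
    if (mm$rate <= 0) next
    eta <- rep(0, n)
    for (d in names(mm$logodds)) {
      parts <- strsplit(d, ":", fixed = TRUE)[[1]]
      val <- rep(1, n)
      for (pt in parts) {
        dv <- if (pt == ".outcome") y else {
          if (anyNA(out[[pt]]))
            stop("MAR driver '", pt, "' must be fully observed", call. = FALSE)
          as.numeric(scale(complete[[pt]]))
        }
        val <- val * dv
      }
      eta <- eta + mm$logodds[[d]] * val
    }
    a <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) - mm$rate,
                        c(-30, 30))$root
    out[[v]][stats::runif(n) < stats::plogis(a + eta)] <- NA
  }
  ospec <- var_spec(gspec$outcome_name, "outcome_raw", "binary")
  spec <- do.call(cohort_spec, c(spec_rows, list(ospec)))
  list(cohort = cohort(out, spec),
       truth = list(intercept = gspec$intercept, coefficients = beta,
                    complete = complete, linear_predictor = lp,
                    probability = prob))
}

#' Preset emulating a primary-care shoulder-pain cohort
#'
#' A ready-made [generator_spec()] shaped like a general-practice shoulder
#' cohort: 587 subjects, about 30 candidate predictors (demographics,
#' complaint characteristics, psychological scale scores, physical
#' factors) with realistic marginals, four true predictors of persistent
#' disability with moderate effects, MAR outcome missingness of about 12\%
#' driven by age and onset (younger subjects with acute onset are more
#' often lost to follow-up), and baseline-predictor missingness between 0
#' and 9.2\%.
#'
#' @return A `generator_spec`.
#' @export
dss_preset <- function() {
  cont <- function(name, mean, sd)
    list(name = name, measurement = "continuous", mean = mean, sd = sd)
  bin <- function(name, prev)
    list(name = name, measurement = "binary", prevalence = prev)
  cat3 <- function(name, probs, levels)
    list(name = name, measurement = "categorical", probs = probs, levels = levels)
  predictors <- list(
    cont("age", 51, 14),
    bin("male", 0.50),
    cat3("education", c(0.36, 0.40, 0.24), c("low", "middle", "high")),
    bin("shoulder_complaints_past", 0.55),
    bin("neck_complaints_past", 0.43),
    cat3("duration", c(0.35, 0.24, 0.41), c("0-6wk", "7-12wk", ">3mo")),
    bin("gradual_onset", 0.62),
    cont("pain_baseline", 4.8, 2),
    cont("disability_baseline", 59.9, 24),
    bin("both_shoulders", 0.13),
    bin("comorbidity", 0.80),
    bin("upper_extremity_pain", 0.42),
    bin("neck_pain", 0.34),
    bin("low_back_pain", 0.24),
    bin("high_back_pain", 0.09),
    bin("psych_complaints", 0.09),
    cont("pain_coping", 2.98, 0.98),
    cont("catastrophizing", 2.2, 0.8),
    cont("internal_locus", 3.3, 0.9),
    cont("external_locus", 3.2, 0.88),
    cont("anxiety", 0.3, 1.2),
    cont("depression", 0.2, 1.3),
    cont("somatisation", 3.3, 4.1),
    cont("distress", 2.3, 4.5),
    cont("fear_avoidance", 14.1, 5.6),
    cont("kinesiophobia", 3.2, 3.5),
    cont("physical_load", 1.2, 1.5),
    cat3("physical_activity", c(0.39, 0.42, 0.19),
         c("less", "equal", "more")),
    cat3("inability_daily", c(0.59, 0.31, 0.10),
         c("none", "1-30d", "1-12mo")),
    bin("sporting_activities", 0.39),
    bin("sporting_injury", 0.05))
  generator_spec(
    n = 587L,
    predictors = predictors,
    correlation = 0.10,
    true_coefficients = c(low_back_pain = 0.65, duration = 0.45,
                          both_shoulders = 0.70, disability_baseline = 0.35),
    intercept = -0.5,
    missingness = list(
      mcar = c(external_locus = 0.056, shoulder_complaints_past = 0.046,
               inability_daily = 0.014, duration = 0.002, somatisation = 0.005,
               disability_baseline = 0.003, kinesiophobia = 0.024),
      mar = list(persistent = list(
        rate = 0.123,
        logodds = c(age = -0.5, gradual_onset = -0.4)))),
    outcome_name = "persistent")
}

#' Preset for structure-recovery and missing-data bias experiments
#'
#' Twelve standard-normal candidate predictors of which `n_true` carry a
#' common true log-odds (default 0.7) and the rest are noise. One true
#' predictor (`x1`) is made missing at random with the missingness
#' probability driven by an observed noise covariate (`x5`), the outcome,
#' and their product — a mechanism under which complete-case estimates of
#' the `x1` coefficient are biased while imputation using the observed
#' drivers is not. Two further predictors carry MCAR holes.
#'
#' @param n Cohort size (default 600).
#' @param beta True log-odds per true predictor (default 0.7).
#' @param n_true,n_noise Counts of true and noise predictors.
#' @param mar_rate Missingness rate on `x1` (default 0.10).
#' @return A `generator_spec`.
#' @export
recovery_preset <- function(n = 600L, beta = 0.7, n_true = 4L, n_noise = 8L,
                            mar_rate = 0.10) {
  p <- n_true + n_noise
  nm <- paste0("x", seq_len(p))
  predictors <- lapply(nm, function(v)
    list(name = v, measurement = "continuous", mean = 0, sd = 1))
  R <- matrix(0.15, p, p); diag(R) <- 1
  R[1, 5] <- R[5, 1] <- 0.45  # x5 is the observed MAR driver for x1
  truec <- stats::setNames(rep(beta, n_true), nm[seq_len(n_true)])
  generator_spec(
    n = n, predictors = predictors, correlation = R,
    true_coefficients = truec, intercept = 0,
    missingness = list(
      mcar = c(x2 = 0.08, x3 = 0.06),
      mar = list(x1 = list(
        rate = mar_rate,
        logodds = c(x5 = 1.0, .outcome = 1.0, `x5:.outcome` = 1.5)))),
    outcome_name = "persistent")
}
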