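# Logistic-regression engine.
#
# All selection procedures run thousands of maximum-likelihood fits on
# resampled rows of the same design matrix, so the matrix is built once per
# data set (design_matrix) and fits go straight through stats::glm.fit
# (logit_irls) without formula overhead. Categorical predictors occupy
# contiguous dummy blocks (reference = first declared level) and always
# enter or leave a model as a whole block.

# Build intercept + dummy-expanded design for `predictors`.
# Returns list(X, blocks) where blocks maps predictor -> column indices.
design_matrix <- function(data, spec, predictors) {
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  blocks <- list()
  at <- 1L
  for (v in predictors) {
    i <- match(v, spec$name)
    if (is.na(i)) stop("predictor '", v, "' not in spec", call. = FALSE)
    if (spec$measurement[i] == "categorical") {
      k <- length(spec$levels[[i]])
      idx <- integer(0)
      for (lev in 2:k) {
        at <- at + 1L
        cols[[paste0(v, ".", spec$levels[[i]][lev])]] <- as.numeric(data[[v]] == lev)
        idx <- c(idx, at)
      }
      blocks[[v]] <- idx
    } else {
      at <- at + 1L
      cols[[v]] <- as.numeric(data[[v]])
      blocks[[v]] <- at
    }
  }
  X <- do.call(cbind, cols)
  list(X = X, blocks = blocks)
}

.fam_binomial <- stats::binomial()

# Maximum-likelihood logistic fit on a ready design matrix.
# Lean Cholesky IRLS for the (full-rank) common case — the selection
# procedures run this hundreds of thousands of times on bootstrap
# resamples — with a fallback to stats::glm.fit's pivoted QR when the
# cross-product is not positive definite (rank-deficient resample), so NA
# coefficients and the true rank keep likelihood-ratio dfs correct.
# Convergence flag is FALSE for IRLS non-convergence or runaway
# coefficients (the separation signature).
logit_irls <- function(X, y) {
  k <- ncol(X)
  beta <- numeric(k)
  eta <- numeric(length(y))
  full_rank <- TRUE
  converged <- FALSE
  for (it in 1:25) {
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w[w < 1e-10] <- 1e-10
    z <- eta + (y - mu) / w
    Xw <- X * w
    ch <- tryCatch(chol(crossprod(X, Xw)), error = function(e) NULL)
    if (is.null(ch)) { full_rank <- FALSE; break }
    beta_new <- drop(backsolve(ch, forwardsolve(t(ch), crossprod(Xw, z))))
    if (any(!is.finite(beta_new))) { full_rank <- FALSE; break }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- drop(X %*% beta)
    if (delta < 1e-8) { converged <- TRUE; break }
    if (max(abs(beta)) > 1e4) break
  }
  if (!full_rank) {
    fit <- suppressWarnings(stats::glm.fit(X, y, family = .fam_binomial))
    p <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
    ll <- sum(y * log(p) + (1 - y) * log1p(-p))
    cf <- fit$coefficients
    return(list(coef = cf, ll = ll, rank = fit$rank,
                converged = isTRUE(fit$converged) && all(abs(cf[!is.na(cf)]) < 30),
                fitted = fit$fitted.values, weights = fit$weights))
  }
  mu <- stats::plogis(eta)
  p <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  list(coef = stats::setNames(beta, colnames(X)), ll = ll, rank = k,
       converged = converged && max(abs(beta)) < 30,
       fitted = mu, weights = mu * (1 - mu))
}

# Intercept-only log-likelihood in closed form.
null_loglik <- function(y) {
  n1 <- sum(y); n <- length(y)
  if (n1 == 0L || n1 == n) return(0)
  n1 * log(n1 / n) + (n - n1) * log(1 - n1 / n)
}

#' Fit a multivariable logistic regression model
#'
#' Standard maximum-likelihood logistic regression, recording the fitted
#' log-likelihood and the intercept-only log-likelihood on the same rows so
#' that likelihood-ratio tests and Nagelkerke R-squared are always
#' computable. Non-convergence or (quasi-)separation is reported through
#' the `converged` flag rather than an error, because resampling procedures
#' must be able to count failed replicates.
#'
#' @param x A [cohort()] with no missing cells among the used columns.
#' @param outcome Name of the binary outcome column.
#' @param predictors Character vector of predictor names (may be empty for
#'   the intercept-only model). Categorical predictors are dummy-expanded
#'   against their first declared level.
#' @return An object of class `logistic_model`: predictors, `intercept`,
#'   dummy-expanded `coefficients` and `se`, `log_likelihood`,
#'   `null_log_likelihood`, `n`, `df` (model rank minus one), `converged`,
#'   and `linear_predictors`/`fitted` on the training rows.
#' @export
fit_logistic <- function(x, outcome, predictors = character()) {
  cols <- c(outcome, predictors)
  dat <- x$data[, cols, drop = FALSE]
  if (nrow(dat) == 0L) stop("empty data", call. = FALSE)
  if (anyNA(dat))
    stop("missing values among used columns; impute or take complete cases first",
         call. = FALSE)
  y <- dat[[outcome]]
  if (length(unique(y)) < 2L)
    stop("outcome '", outcome, "' has a single class", call. = FALSE)
  dm <- design_matrix(dat, x$spec, predictors)
  f <- logit_irls(dm$X, y)
  # observed-information covariance for Rubin pooling
  w <- f$weights
  ok <- !is.na(f$coef)
  info <- crossprod(dm$X[, ok, drop = FALSE] * w, dm$X[, ok, drop = FALSE])
  se <- rep(NA_real_, length(f$coef))
  vc <- try(chol2inv(chol(info)), silent = TRUE)
  if (!inherits(vc, "try-error")) se[ok] <- sqrt(diag(vc))
  names(se) <- colnames(dm$X)
  structure(list(predictors = predictors,
                 intercept = unname(f$coef[1]),
                 coefficients = f$coef[-1],
                 se = se[-1],
                 intercept_se = unname(se[1]),
                 log_likelihood = f$ll,
                 null_log_likelihood = null_loglik(y),
                 n = length(y),
                 df = f$rank - 1L,
                 converged = f$converged,
                 blocks = dm$blocks,
                 spec = x$spec,
                 linear_predictors = drop(dm$X[, ok, drop = FALSE] %*% f$coef[ok]),
                 fitted = f$fitted),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("<logistic_model> n =", x$n, "\n")
  cat("  predictors:", if (length(x$predictors)) paste(x$predictors, collapse = ", ")
      else "(intercept only)", "\n")
  cat("  logLik =", format(x$log_likelihood, digits = 6),
      " null =", format(x$null_log_likelihood, digits = 6),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  if (length(x$coefficients)) {
    print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  } else cat("  intercept =", round(x$intercept, 4), "\n")
  invisible(x)
}

#' Predicted event probabilities
#'
#' @param object A `logistic_model`.
#' @param newdata A [cohort()] (or data frame) with the model's predictors.
#' @param type `"response"` for probabilities, `"link"` for log-odds.
#' @param ... Unused.
#' @export
predict.logistic_model <- function(object, newdata = NULL,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    lp <- object$linear_predictors
  } else {
    dat <- if (inherits(newdata, "cohort")) newdata$data else newdata
    spec <- if (inherits(newdata, "cohort")) newdata$spec else object$spec
    dm <- design_matrix(dat, spec, object$predictors)
    cf <- c(object$intercept, object$coefficients)
    cf[is.na(cf)] <- 0
    lp <- drop(dm$X %*% cf)
  }
  if (type == "link") lp else stats::plogis(lp)
}
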