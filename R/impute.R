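# Multiple imputation by chained equations (MICE) with predictive mean
# matching (PMM).
#
# Each variable with missing cells gets a conditional linear model on all
# other variables (current completed values, categorical predictors
# dummy-expanded). A missing cell is filled with the *observed* value of a
# donor whose predicted mean lies closest to the target's predicted mean;
# donor predictions use a Bayesian draw of the regression coefficients,
# target predictions the posterior-mean coefficients, so matching reflects
# parameter uncertainty (type-1 matching). Because every imputed value is a
# donated observed value, binary and categorical variables can share the
# same engine and never receive an implausible code.

#' Impute missing values by chained equations with PMM
#'
#' @param x A [cohort()].
#' @param m Number of imputed data sets (default 5; up to about 20 is a
#'   sensible advisory ceiling).
#' @param n_iter Chained-equation cycles per imputation (default 10).
#' @param k_donors Donor-pool size for PMM (default 5).
#' @param seed Integer seed; each imputation runs on an independent
#'   sub-stream so results are bit-reproducible.
#' @param exclude Variables never used as imputation predictors (e.g. id
#'   columns). Variables with role `"id"` are excluded automatically.
#' @return An object of class `imputation_result`: `completed` (list of m
#'   complete [cohort()]s), `m`, `n_iter`, `k_donors`, `seed`, and `trace`
#'   (per-chain, per-iteration mean/SD of the imputed cells per variable).
#' @export
impute <- function(x, m = 5L, n_iter = 10L, k_donors = 5L, seed = 1L,
                   exclude = character()) {
  spec <- x$spec
  dat <- x$data
  exclude <- union(exclude, spec$name[spec$role == "id"])
  vars <- setdiff(names(dat), exclude)
  n_mis <- vapply(dat[vars], function(col) sum(is.na(col)), integer(1))
  targets <- vars[n_mis > 0]
  for (v in targets) {
    if (sum(!is.na(dat[[v]])) < k_donors)
      stop("variable '", v, "' has fewer than k_donors = ", k_donors,
           " observed values", call. = FALSE)
  }
  if (length(targets) == 0L) {
    completed <- replicate(m, x, simplify = FALSE)
    return(structure(list(completed = completed, m = as.integer(m),
                          n_iter = as.integer(n_iter), k_donors = as.integer(k_donors),
                          seed = as.integer(seed),
                          trace = empty_trace()),
                     class = "imputation_result"))
  }
  # visit in increasing missingness
  targets <- targets[order(n_mis[targets], match(targets, vars))]
  seeds <- split_seeds(seed, m, tag = 101L)
  trace <- vector("list", m)
  completed <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(seeds[i])
    res <- mice_chain(dat, spec, vars, targets, n_iter, k_donors)
    completed[[i]] <- cohort(res$filled, spec)
    tr <- res$trace
    if (nrow(tr)) tr$chain <- i
    trace[[i]] <- tr
  }
  structure(list(completed = completed, m = as.integer(m),
                 n_iter = as.integer(n_iter), k_donors = as.integer(k_donors),
                 seed = as.integer(seed),
                 trace = do.call(rbind, trace)),
            class = "imputation_result")
}

empty_trace <- function() {
  data.frame(chain = integer(), iteration = integer(), variable = character(),
             mean = numeric(), sd = numeric(), stringsAsFactors = FALSE)
}

# One chained-equations run (single imputation). Assumes RNG already seeded.
mice_chain <- function(dat, spec, vars, targets, n_iter, k_donors) {
  mis_idx <- lapply(dat, function(col) which(is.na(col)))
  filled <- dat
  # initialize by random draws from the observed marginals
  for (v in targets) {
    obs <- filled[[v]][!is.na(filled[[v]])]
    filled[[v]][mis_idx[[v]]] <- sample(obs, length(mis_idx[[v]]), replace = TRUE)
  }
  trace <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    for (v in targets) {
      idx <- mis_idx[[v]]
      preds <- setdiff(vars, v)
      dm <- design_matrix(filled, spec, preds)
      obs <- which(!is.na(dat[[v]]))  # regress on originally observed cells only
      filled[[v]][idx] <- pmm_draw(dm$X, dat[[v]], obs, idx, k_donors)
    }
    trace[[it]] <- do.call(rbind, lapply(targets, function(v) {
      imp <- filled[[v]][mis_idx[[v]]]
      data.frame(chain = NA_integer_, iteration = it, variable = v,
                 mean = mean(imp), sd = stats::sd(imp), stringsAsFactors = FALSE)
    }))
  }
  list(filled = filled, trace = do.call(rbind, trace))
}

# Draw PMM imputations for the missing cells of one variable.
# X: full design (intercept + all other variables, current completed data);
# y: the variable's original values (NA at missing); obs/idx: row indices.
pmm_draw <- function(X, y, obs, idx, k_donors) {
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  XtX <- crossprod(Xo)
  Xty <- crossprod(Xo, yo)
  p <- ncol(Xo)
  R <- try(chol(XtX), silent = TRUE)
  if (inherits(R, "try-error")) {
    # ridge-stabilized fallback for singular conditional regressions
    warning("singular conditional regression; ridge-stabilized", call. = FALSE)
    XtX <- XtX + diag(1e-5 * mean(diag(XtX)), p)
    R <- chol(XtX)
  }
  beta_hat <- backsolve(R, forwardsolve(t(R), Xty))
  resid <- yo - drop(Xo %*% beta_hat)
  df <- max(length(obs) - p, 1L)
  sse <- sum(resid^2)
  sigma2_star <- sse / stats::rchisq(1L, df)
  # beta* ~ N(beta_hat, sigma2* (X'X)^-1), via the Cholesky of (X'X)^-1
  beta_star <- beta_hat + backsolve(R, stats::rnorm(p)) * sqrt(sigma2_star)
  pred_donor <- drop(Xo %*% beta_star)          # donors: Bayesian draw
  pred_target <- drop(X[idx, , drop = FALSE] %*% beta_hat)  # targets: posterior mean
  k <- min(k_donors, length(obs))
  vapply(pred_target, function(pt) {
    d <- abs(pred_donor - pt)
    pool <- order(d)[seq_len(k)]
    yo[pool[sample.int(k, 1L)]]
  }, numeric(1))
}

#' Chain summaries of imputed cells for mixing diagnostics
#'
#' @param result An [impute()] result with `n_iter >= 2` (a single-iteration
#'   trace is returned with a warning).
#' @return A data frame with columns `chain`, `iteration`, `variable`,
#'   `mean`, `sd`; empty when the input had no missing cells.
#' @export
convergence_trace <- function(result) {
  stopifnot(inherits(result, "imputation_result"))
  if (result$n_iter < 2L && nrow(result$trace))
    warning("single-iteration run: trace cannot show mixing", call. = FALSE)
  result$trace
}

#' Write completed data sets as indexed CSV files
#'
#' @param result An [impute()] result.
#' @param dir Output directory; files are named `imp_1.csv` ... `imp_m.csv`.
#' @export
write_imputations <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(result$m))
    write_cohort(result$completed[[i]], file.path(dir, sprintf("imp_%d.csv", i)))
  invisible(dir)
}
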