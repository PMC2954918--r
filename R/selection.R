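# Backward elimination with a likelihood-ratio stopping rule, and the
# pooling rules that carry variable selection across multiply imputed data
# sets: the inclusion-fraction qualification, a pooled likelihood-ratio
# confirmation, and Rubin's rules for coefficients.

# Core eliminator working directly on a prebuilt design matrix, so the
# bootstrap procedures can run thousands of eliminations cheaply.
# X: full design (intercept first), blocks: predictor -> column indices,
# canonical: tie-break order. Returns the surviving predictor set, the
# removal trace and a convergence flag for the whole path.
backward_core <- function(X, y, blocks, start, alpha, canonical) {
  active <- canonical_sort(start, canonical)
  trace <- data.frame(removed = character(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  path_ok <- TRUE
  cols_of <- function(set) c(1L, unlist(blocks[set], use.names = FALSE))
  full <- logit_irls(X[, cols_of(active), drop = FALSE], y)
  if (!full$converged) path_ok <- FALSE
  while (length(active)) {
    fits <- lapply(active, function(v)
      logit_irls(X[, cols_of(setdiff(active, v)), drop = FALSE], y))
    ps <- vapply(seq_along(active), function(j) {
      stat <- max(0, 2 * (full$ll - fits[[j]]$ll))
      df <- max(full$rank - fits[[j]]$rank, 1L)
      stats::pchisq(stat, df, lower.tail = FALSE)
    }, numeric(1))
    worst <- max(ps)
    if (worst <= alpha) break
    # ties: remove the predictor later in canonical order
    cand <- which(ps == worst)
    j <- cand[length(cand)]
    trace <- rbind(trace, data.frame(removed = active[j], p_value = worst,
                                     stringsAsFactors = FALSE))
    full <- fits[[j]]
    if (!full$converged) path_ok <- FALSE
    active <- active[-j]
  }
  list(retained = active, trace = trace, converged = path_ok, fit = full)
}

#' Backward elimination with a likelihood-ratio stopping rule
#'
#' Repeatedly fits the current model and, for each remaining predictor,
#' the model without it; the predictor with the largest drop-one
#' likelihood-ratio p-value is removed while that p-value exceeds `alpha`
#' (default 0.157, chosen for comparability with AIC-based selection).
#' Categorical predictors leave as complete dummy blocks. Ties on p are
#' broken by removing the predictor later in canonical (spec) order, so the
#' result is invariant to the order predictors are supplied in.
#'
#' @param x A [cohort()] complete on the used columns.
#' @param outcome Binary outcome name.
#' @param start Non-empty starting predictor set.
#' @param alpha Stopping level in (0,1).
#' @return A list of class `backward_fit`: `model` (a refit
#'   [fit_logistic()] model of the survivors), `retained`, `trace`
#'   (ordered removals with p-values), `converged`.
#' @export
backward_eliminate <- function(x, outcome, start, alpha = 0.157) {
  stopifnot(length(start) >= 1, alpha > 0, alpha < 1)
  y <- x$data[[outcome]]
  dm <- design_matrix(x$data, x$spec, start)
  canonical <- intersect(x$spec$name, start)
  res <- backward_core(dm$X, y, dm$blocks, start, alpha, canonical)
  structure(list(model = fit_logistic(x, outcome, res$retained),
                 retained = res$retained, trace = res$trace,
                 converged = res$converged),
            class = "backward_fit")
}

# Pooled likelihood-ratio test across m imputed data sets (drop `drop_var`
# from `full_set`). Pools the per-imputation LR statistics with an
# average-relative-increase correction and an F reference; degenerates to
# the plain chi-square test at m = 1. A median-p fallback is available for
# cross-checking.
pooled_lrt <- function(imps, outcome, full_set, drop_var, method = "D2") {
  stats_m <- vapply(imps$completed, function(ci) {
    f1 <- fit_logistic(ci, outcome, full_set)
    f0 <- fit_logistic(ci, outcome, setdiff(full_set, drop_var))
    c(stat = max(0, 2 * (f1$log_likelihood - f0$log_likelihood)),
      df = f1$df - f0$df)
  }, numeric(2))
  d <- stats_m["stat", ]
  k <- max(stats_m["df", 1], 1L)
  m <- length(d)
  if (method == "median_p")
    return(stats::median(stats::pchisq(d, k, lower.tail = FALSE)))
  if (m == 1L)
    return(stats::pchisq(d, k, lower.tail = FALSE))
  r <- (1 + 1 / m) * stats::var(sqrt(d))
  D2 <- (mean(d) / k - (m + 1) / (m - 1) * r) / (1 + r)
  if (!is.finite(D2) || D2 < 0) D2 <- 0
  nu <- if (r > 0) k^(-3 / m) * (m - 1) * (1 + 1 / r)^2 else Inf
  if (is.finite(nu)) stats::pf(D2, k, nu, lower.tail = FALSE)
  else stats::pchisq(D2 * k, k, lower.tail = FALSE)
}

#' Variable selection across multiply imputed data sets
#'
#' The multiple-imputation selection strategy: (1) each completed data set
#' is univariably screened; candidates screened-in in at least
#' `inclusion_threshold` of the data sets form the starting pool. (2)
#' Backward elimination runs in each completed data set from that pool; the
#' inclusion fraction of each predictor over the m final models is
#' tabulated, and predictors appearing in at least `inclusion_threshold` of
#' the models (>= 2 of 5 at defaults) qualify for the final model. (3) Each
#' qualified predictor is confirmed by a pooled likelihood-ratio test
#' (drop-one from the qualified set, pooled across imputations); predictors
#' with pooled p > `alpha_lrt` are removed iteratively, largest p first.
#'
#' @param imps An [impute()] result.
#' @param outcome Binary outcome name.
#' @param candidates Candidate predictors (already past the collinearity
#'   filter).
#' @param config An [analysis_config()].
#' @return A list of class `mi_selection`: `models` (per-imputation refits
#'   of the confirmed set), `inclusion` (an inclusion table over the m
#'   per-imputation final models), `confirmed`, `dropped_confirmation`
#'   (name/p pairs removed in step 3), `screened` (per-imputation screen
#'   results), `pool` (the screened-in starting pool).
#' @export
mi_select <- function(imps, outcome, candidates, config = analysis_config()) {
  m <- imps$m
  screened <- lapply(imps$completed, function(ci)
    univariable_screen(ci, outcome, candidates, config$alpha_univariable))
  frac_in <- vapply(candidates, function(v)
    mean(vapply(screened, function(s) v %in% s$retained, logical(1))), numeric(1))
  pool <- candidates[frac_in >= config$inclusion_threshold]
  if (length(pool) == 0L) {
    warning("no candidate survived pooled univariable screening; intercept-only result",
            call. = FALSE)
    models <- lapply(imps$completed, fit_logistic, outcome = outcome)
    return(structure(list(models = models,
                          inclusion = inclusion_table(list(), candidates),
                          confirmed = character(),
                          dropped_confirmation = data.frame(name = character(),
                                                            p_value = numeric()),
                          screened = screened, pool = pool),
                     class = "mi_selection"))
  }
  finals <- lapply(imps$completed, function(ci)
    backward_eliminate(ci, outcome, pool, config$alpha_backward)$retained)
  inclusion <- inclusion_table(finals, pool)
  qualified <- inclusion$predictor[inclusion$fraction >= config$inclusion_threshold]
  qualified <- canonical_sort(qualified, imps$completed[[1]]$spec$name)
  dropped <- data.frame(name = character(), p_value = numeric(),
                        stringsAsFactors = FALSE)
  # iterative pooled-LRT confirmation, largest pooled p first
  while (length(qualified)) {
    ps <- vapply(qualified, function(v)
      pooled_lrt(imps, outcome, qualified, v, config$lrt_pool), numeric(1))
    if (max(ps) <= config$alpha_lrt) break
    j <- which(ps == max(ps))
    j <- j[length(j)]
    dropped <- rbind(dropped, data.frame(name = qualified[j], p_value = max(ps),
                                         stringsAsFactors = FALSE))
    qualified <- qualified[-j]
  }
  if (length(qualified) == 0L)
    warning("no predictor survived pooled-LRT confirmation; intercept-only result",
            call. = FALSE)
  models <- lapply(imps$completed, fit_logistic, outcome = outcome,
                   predictors = qualified)
  structure(list(models = models, inclusion = inclusion, confirmed = qualified,
                 dropped_confirmation = dropped, screened = screened, pool = pool),
            class = "mi_selection")
}

# Tabulate how often each predictor appears in a list of final models.
inclusion_table <- function(finals, predictors) {
  counts <- vapply(predictors, function(v)
    sum(vapply(finals, function(f) v %in% f, logical(1))), integer(1))
  total <- length(finals)
  data.frame(predictor = predictors, count = unname(counts),
             fraction = if (total) unname(counts) / total else rep(NA_real_,
                                                                   length(predictors)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pool coefficients across imputations by Rubin's rules
#'
#' Pooled estimate = mean of per-imputation estimates; total variance =
#' mean within-imputation variance + (1 + 1/m) times the between-imputation
#' variance, per coefficient.
#'
#' @param models List of `logistic_model`s sharing one composition.
#' @return A data frame: `term`, `estimate`, `within_var`, `between_var`,
#'   `total_var`, `se`.
#' @export
pool_rubin <- function(models) {
  comps <- unique(vapply(models, function(mo)
    paste(sort(mo$predictors), collapse = "+"), character(1)))
  if (length(comps) != 1L)
    stop("models do not share an identical composition", call. = FALSE)
  m <- length(models)
  est <- sapply(models, function(mo) c(`(Intercept)` = mo$intercept, mo$coefficients))
  vwith <- sapply(models, function(mo) c(mo$intercept_se, mo$se)^2)
  if (is.null(dim(est))) { est <- matrix(est, nrow = 1); vwith <- matrix(vwith, nrow = 1) }
  terms <- c("(Intercept)", names(models[[1]]$coefficients))
  qbar <- rowMeans(est)
  ubar <- rowMeans(vwith)
  b <- if (m > 1) apply(est, 1, stats::var) else rep(0, length(qbar))
  tot <- ubar + (1 + 1 / m) * b
  data.frame(term = terms, estimate = unname(qbar), within_var = unname(ubar),
             between_var = unname(b), total_var = unname(tot),
             se = sqrt(unname(tot)), row.names = NULL, stringsAsFactors = FALSE)
}
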