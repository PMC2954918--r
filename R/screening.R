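# Preprocessing chain: outcome construction, linearity handling,
# collinearity filter, univariable pre-selection and the events-per-variable
# power check.

#' Relative change from baseline
#'
#' Fractional improvement of a symptom score: `(baseline - followup) /
#' baseline`. Positive values are improvement, negative values worsening.
#' Subjects with a zero baseline have no defined relative change; they are
#' returned as `NA` and flagged (attribute `undefined`) rather than silently
#' dropped.
#'
#' @param baseline,followup Numeric score vectors of equal length.
#' @return Numeric vector of relative changes, with attribute `undefined`
#'   holding the indices of zero-baseline subjects (warned about).
#' @export
relative_change <- function(baseline, followup) {
  stopifnot(length(baseline) == length(followup))
  out <- (baseline - followup) / baseline
  undef <- which(!is.na(baseline) & baseline == 0)
  if (length(undef)) {
    warning("relative change undefined for ", length(undef),
            " subject(s) with zero baseline; returned NA", call. = FALSE)
    out[undef] <- NA_real_
  }
  attr(out, "undefined") <- undef
  out
}

#' Dichotomize a change score into a persistence indicator
#'
#' Subjects improving less than the cut-off are labelled persistent
#' (indicator 1). Improvement of exactly the cut-off counts as improved
#' (strict `<`).
#'
#' @param change Relative change vector (see [relative_change()]).
#' @param cutoff Fractional improvement threshold in (0, 1]; default 0.5.
#' @return Integer 0/1 vector (`NA` propagated).
#' @export
dichotomize_outcome <- function(change, cutoff = 0.5) {
  stopifnot(cutoff > 0, cutoff <= 1)
  as.integer(change < cutoff)
}

#' ROC-style optimal cut-off against an external criterion
#'
#' Evaluates every distinct observed change value plus adjacent midpoints as
#' a threshold (classify "recovered" when change >= threshold) and returns
#' the threshold minimizing total misclassification against the external
#' recovery criterion. Ties are broken toward the threshold nearest 0.5.
#'
#' @param changes Numeric change scores.
#' @param recovered 0/1 external criterion (e.g. patient-perceived
#'   recovery), same length, both classes present.
#' @return A list of class `cutoff_result`: `threshold`,
#'   `misclassification`, `sensitivity`, `specificity`.
#' @export
optimal_cutoff <- function(changes, recovered) {
  stopifnot(length(changes) == length(recovered), length(changes) >= 2)
  ok <- !is.na(changes) & !is.na(recovered)
  changes <- changes[ok]; recovered <- recovered[ok]
  if (length(unique(recovered)) < 2L)
    stop("external criterion has a single class", call. = FALSE)
  v <- sort(unique(changes))
  cand <- sort(unique(c(v, (v[-1] + v[-length(v)]) / 2)))
  n1 <- sum(recovered == 1)
  n0 <- sum(recovered == 0)
  mis <- vapply(cand, function(thr) {
    pred <- as.integer(changes >= thr)
    sum(pred != recovered)
  }, numeric(1))
  best <- which(mis == min(mis))
  pick <- best[which.min(abs(cand[best] - 0.5))]
  thr <- cand[pick]
  pred <- as.integer(changes >= thr)
  structure(list(threshold = thr,
                 misclassification = sum(pred != recovered),
                 sensitivity = sum(pred == 1 & recovered == 1) / n1,
                 specificity = sum(pred == 0 & recovered == 0) / n0),
            class = "cutoff_result")
}

#' Check whether a continuous predictor can stay linear in the logit
#'
#' Fits the outcome on the linear term alone and on the linear term plus
#' quantile-group indicators; a likelihood-ratio test of the group block
#' measures departure from linearity. When the departure is not significant
#' the recommendation is to keep the variable linear, otherwise to
#' categorize it at the quantile cut points (tertiles for 3 groups, the
#' median for 2).
#'
#' @param x Continuous predictor values.
#' @param y Binary outcome indicators.
#' @param n_groups 2 or 3.
#' @param alpha Significance level for the nonlinearity test. The default
#'   0.05 is the conventional level for assumption checks; at more liberal
#'   levels truly linear predictors would be categorized (and information
#'   lost) in a correspondingly larger share of cohorts.
#' @return A list: `recommendation` (`"keep linear"` / `"categorize"`),
#'   `p_value`, `cut_points`.
#' @export
linearity_check <- function(x, y, n_groups = 3L, alpha = 0.05) {
  stopifnot(n_groups %in% c(2L, 3L))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < n_groups)
    stop("predictor has fewer distinct values than groups", call. = FALSE)
  qs <- stats::quantile(x, probs = seq_len(n_groups - 1L) / n_groups, names = FALSE)
  grp <- cut(x, breaks = c(-Inf, qs, Inf), labels = FALSE)
  if (length(unique(grp)) < n_groups)
    stop("degenerate quantile groups (ties collapse a category)", call. = FALSE)
  Xlin <- cbind(1, x)
  dummies <- sapply(2:n_groups, function(g) as.numeric(grp == g))
  Xfull <- cbind(Xlin, dummies)
  f0 <- logit_irls(Xlin, y)
  f1 <- logit_irls(Xfull, y)
  stat <- max(0, 2 * (f1$ll - f0$ll))
  df <- f1$rank - f0$rank
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(recommendation = if (p <= alpha) "categorize" else "keep linear",
       p_value = p, cut_points = qs)
}

#' Collinearity filter with clinical-priority tie resolution
#'
#' Computes pairwise Pearson correlations on pairwise-complete observations
#' among the candidate predictors. Pairs with `|r| >= r_threshold` are
#' processed in decreasing `|r|`; in each still-active pair the variable
#' with the worse (numerically larger) clinical priority is dropped — the
#' variable easiest to obtain in clinical practice is retained. A variable
#' already dropped cannot cause further drops.
#'
#' @param x A [cohort()].
#' @param candidates Candidate predictor names.
#' @param r_threshold Absolute-correlation trigger, default 0.5.
#' @return A list: `retained`, and `dropped` — a data frame with columns
#'   `dropped`, `kept`, `r`.
#' @export
collinearity_filter <- function(x, candidates, r_threshold = 0.5) {
  stopifnot(r_threshold > 0, r_threshold <= 1)
  dat <- x$data[, candidates, drop = FALSE]
  R <- suppressWarnings(stats::cor(dat, use = "pairwise.complete.obs"))
  pairs <- which(upper.tri(R) & abs(R) >= r_threshold & !is.na(R), arr.ind = TRUE)
  log <- data.frame(dropped = character(), kept = character(), r = numeric(),
                    stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    # decreasing |r|; deterministic tie-break on names
    o <- order(-abs(R[pairs]), candidates[pairs[, 1]], candidates[pairs[, 2]])
    pairs <- pairs[o, , drop = FALSE]
    dropped <- character()
    pri <- x$spec$clinical_priority[match(candidates, x$spec$name)]
    names(pri) <- candidates
    for (k in seq_len(nrow(pairs))) {
      a <- candidates[pairs[k, 1]]; b <- candidates[pairs[k, 2]]
      if (a %in% dropped || b %in% dropped) next
      if (is.na(pri[a]) || is.na(pri[b]))
        stop("clinical_priority missing for correlated pair ", a, " / ", b,
             call. = FALSE)
      loser <- if (pri[a] > pri[b]) a else b
      keeper <- setdiff(c(a, b), loser)
      dropped <- c(dropped, loser)
      log <- rbind(log, data.frame(dropped = loser, kept = keeper,
                                   r = unname(R[pairs[k, 1], pairs[k, 2]]),
                                   stringsAsFactors = FALSE))
    }
    candidates <- setdiff(candidates, dropped)
  }
  list(retained = candidates, dropped = log)
}

#' Univariable pre-selection of candidate predictors
#'
#' Fits one logistic model per candidate (categorical candidates as a full
#' dummy block, tested by a block likelihood-ratio test against the
#' intercept-only model) and retains candidates with p <= alpha. A
#' perfectly separating candidate cannot be assessed by the LRT p-value and
#' is retained with p recorded as 0 plus a convergence warning.
#'
#' @param x A [cohort()] complete on the used columns.
#' @param outcome Binary outcome name.
#' @param candidates Candidate names.
#' @param alpha Retention level, default 0.157.
#' @return A list: `retained`, `dropped` (data frame name/p_value),
#'   `p_values` (named, all candidates).
#' @export
univariable_screen <- function(x, outcome, candidates, alpha = 0.157) {
  y <- x$data[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("outcome has a single class", call. = FALSE)
  res <- screen_core(x$data, x$spec, y, candidates, alpha)
  res
}

# Matrix-level screen shared with the bootstrap path.
screen_core <- function(data, spec, y, candidates, alpha) {
  ll0 <- null_loglik(y)
  p_values <- vapply(candidates, function(v) {
    dm <- design_matrix(data, spec, v)
    f <- logit_irls(dm$X, y)
    if (!f$converged) {
      warning("perfect separation on candidate '", v, "'; retained with p = 0",
              call. = FALSE)
      return(0)
    }
    stat <- max(0, 2 * (f$ll - ll0))
    stats::pchisq(stat, f$rank - 1L, lower.tail = FALSE)
  }, numeric(1))
  keep <- p_values <= alpha
  list(retained = candidates[keep],
       dropped = data.frame(name = candidates[!keep],
                            p_value = unname(p_values[!keep]),
                            stringsAsFactors = FALSE),
       p_values = p_values)
}

#' Events per variable
#'
#' The number of events — conservatively, the minority outcome class —
#' divided by the number of candidate predictors. Values at or below
#' `epv_min` trigger a power warning: the rule of thumb requires more than
#' 10 events per modelled variable.
#'
#' @param x A [cohort()].
#' @param outcome Binary outcome name.
#' @param n_candidates Number of candidate predictors (>= 1).
#' @param epv_min Warning floor, default 10.
#' @return EPV value (events / n_candidates), with attribute `events`.
#' @export
events_per_variable <- function(x, outcome, n_candidates, epv_min = 10) {
  stopifnot(n_candidates >= 1)
  y <- x$data[[outcome]]
  y <- y[!is.na(y)]
  events <- min(sum(y == 1), sum(y == 0))
  if (events == 0L) stop("zero events: outcome has a single class", call. = FALSE)
  epv <- events / n_candidates
  if (epv <= epv_min)
    warning(sprintf("EPV = %.1f <= %s: analysis may be underpowered", epv, epv_min),
            call. = FALSE)
  structure(epv, events = events)
}
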