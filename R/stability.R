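# Two-step bootstrap model selection: step 1 qualifies predictors by their
# bootstrap inclusion fraction; step 2 re-runs selection on fresh bootstrap
# samples restricted to the qualified set and tabulates how often each
# model composition is chosen — the model-selection frequency table that
# quantifies stability.

#' Tabulate bootstrap model compositions
#'
#' @param compositions List of character vectors (predictor sets).
#' @param canonical Canonical predictor ordering (spec order).
#' @param failed Number of non-converged replicates excluded from the
#'   denominator.
#' @return A `frequency_table`: data frame with `composition`, `count`,
#'   `percent`, sorted by count descending (ties lexicographic), plus
#'   attributes `total_models` and `failed_replicates`.
#' @export
frequency_table <- function(compositions, canonical, failed = 0L) {
  keys <- vapply(compositions, composition_key, character(1), canonical = canonical)
  tab <- table(keys)
  out <- data.frame(composition = as.character(names(tab) %||% character()),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  if (nrow(out)) out <- out[order(-out$count, out$composition), , drop = FALSE]
  total <- length(keys)
  out$percent <- 100 * out$count / total
  rownames(out) <- NULL
  structure(out, total_models = total, failed_replicates = as.integer(failed),
            class = c("frequency_table", "data.frame"))
}

#' @export
print.frequency_table <- function(x, top = 10L, ...) {
  cat("<frequency_table> ", attr(x, "total_models"), " models (",
      attr(x, "failed_replicates"), " failed replicates excluded)\n", sep = "")
  y <- utils::head(as.data.frame(x), top)
  y$percent <- sprintf("%.1f", y$percent)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Per-predictor inclusion fractions and ranks from a frequency table
#'
#' The fraction is the share of tabulated models whose composition contains
#' the predictor; ranks are by descending fraction with ties resolved by
#' canonical order.
#'
#' @param freq A [frequency_table()].
#' @param predictors Predictors to rank (defaults to every predictor
#'   appearing in any composition).
#' @param canonical Canonical ordering used for tie-breaks; defaults to
#'   `predictors`.
#' @return Data frame: `predictor`, `fraction`, `rank`.
#' @export
rank_predictors <- function(freq, predictors = NULL, canonical = NULL) {
  total <- attr(freq, "total_models")
  stopifnot(total >= 1)
  sets <- strsplit(freq$composition, " \\+ ")
  sets[freq$composition == "(intercept only)"] <- list(character())
  if (is.null(predictors)) predictors <- unique(unlist(sets))
  if (is.null(canonical)) canonical <- predictors
  predictors <- canonical_sort(predictors, canonical)
  frac <- vapply(predictors, function(v)
    sum(freq$count[vapply(sets, function(s) v %in% s, logical(1))]) / total,
    numeric(1))
  o <- order(-frac, match(predictors, canonical))
  data.frame(predictor = predictors[o], fraction = unname(frac[o]),
             rank = seq_along(predictors), row.names = NULL,
             stringsAsFactors = FALSE)
}

# One full selection path on a bootstrap resample: univariable screen
# (optional), then backward elimination. Returns NULL for a failed
# (non-converged) replicate, otherwise the surviving predictor set.
boot_replicate <- function(X, y, blocks, candidates, spec, data, alpha_uni,
                           alpha_back, canonical, screen = TRUE, idx) {
  yb <- y[idx]
  if (length(unique(yb)) < 2L) return(NULL)
  Xb <- X[idx, , drop = FALSE]
  start <- candidates
  if (screen) {
    ll0 <- null_loglik(yb)
    keep <- vapply(candidates, function(v) {
      cols <- c(1L, blocks[[v]])
      f <- logit_irls(Xb[, cols, drop = FALSE], yb)
      if (!f$converged) return(TRUE)  # separation: retain, p treated as 0
      stat <- max(0, 2 * (f$ll - ll0))
      stats::pchisq(stat, max(f$rank - 1L, 1L), lower.tail = FALSE) <= alpha_uni
    }, logical(1))
    start <- candidates[keep]
  }
  if (length(start) == 0L) return(character())
  res <- backward_core(Xb, yb, blocks, start, alpha_back, canonical)
  if (!res$converged) return(NULL)
  res$retained
}

#' Two-step bootstrap model selection on one complete data set
#'
#' Step 1 draws `b_step1` bootstrap resamples; in each, the candidates are
#' univariably screened and backward elimination is run on the screened
#' set, so the whole selection path is resampled. Predictors appearing in
#' at least `inclusion_threshold` of the successful step-1 models qualify.
#' Step 2 draws `b_step2` fresh resamples (independent random stream) and
#' reruns backward elimination from the qualified set only; the resulting
#' model compositions are tabulated into a model-selection frequency table.
#' Non-converging replicates are counted and excluded from denominators,
#' never redrawn (redrawing would bias toward well-behaved resamples); a
#' warning is raised when failures exceed 5 percent.
#'
#' @param x A [cohort()] with no missing cells among the used columns.
#' @param outcome Binary outcome name.
#' @param candidates Candidate predictor names.
#' @param config An [analysis_config()].
#' @param seed Integer seed.
#' @return A list of class `stability_result`: `step1_inclusion`,
#'   `qualified`, `step2_frequencies` (a [frequency_table()]),
#'   `final_rank` (via [rank_predictors()]), `failed_step1`,
#'   `failed_step2`.
#' @export
bootstrap_select <- function(x, outcome, candidates,
                             config = analysis_config(), seed = 1L) {
  dat <- x$data[, c(outcome, candidates), drop = FALSE]
  if (anyNA(dat))
    stop("bootstrap selection needs complete data; impute or take complete cases",
         call. = FALSE)
  y <- dat[[outcome]]
  dm <- design_matrix(dat, x$spec, candidates)
  canonical <- intersect(x$spec$name, candidates)
  n <- nrow(dat)
  seeds <- split_seeds(seed, 2L, tag = 202L)

  run_step <- function(b, step_seed, cands, screen) {
    set.seed(step_seed)
    out <- vector("list", b)
    for (i in seq_len(b)) {
      idx <- sample.int(n, n, replace = TRUE)
      out[[i]] <- boot_replicate(dm$X, y, dm$blocks, cands, x$spec, dat,
                                 config$alpha_univariable, config$alpha_backward,
                                 canonical, screen = screen, idx = idx)
    }
    out
  }

  s1 <- run_step(config$b_step1, seeds[1], candidates, screen = TRUE)
  ok1 <- !vapply(s1, is.null, logical(1))
  failed1 <- sum(!ok1)
  if (failed1 > 0.05 * config$b_step1)
    warning(sprintf("step 1: %d of %d replicates failed to converge",
                    failed1, config$b_step1), call. = FALSE)
  incl <- inclusion_table(s1[ok1], candidates)
  qualified <- incl$predictor[!is.na(incl$fraction) &
                                incl$fraction >= config$inclusion_threshold]
  qualified <- canonical_sort(qualified, canonical)
  if (length(qualified) == 0L) {
    warning("no predictor qualified after bootstrap step 1", call. = FALSE)
    freq <- frequency_table(list(), canonical)
    return(structure(list(step1_inclusion = incl, qualified = qualified,
                          step2_frequencies = freq,
                          final_rank = data.frame(predictor = character(),
                                                  fraction = numeric(),
                                                  rank = integer()),
                          failed_step1 = failed1, failed_step2 = 0L),
                     class = "stability_result"))
  }
  s2 <- run_step(config$b_step2, seeds[2], qualified, screen = FALSE)
  ok2 <- !vapply(s2, is.null, logical(1))
  failed2 <- sum(!ok2)
  if (failed2 > 0.05 * config$b_step2)
    warning(sprintf("step 2: %d of %d replicates failed to converge",
                    failed2, config$b_step2), call. = FALSE)
  freq <- frequency_table(s2[ok2], canonical, failed = failed2)
  structure(list(step1_inclusion = incl, qualified = qualified,
                 step2_frequencies = freq,
                 final_rank = rank_predictors(freq, qualified, canonical),
                 failed_step1 = failed1, failed_step2 = failed2),
            class = "stability_result")
}

#' Two-step bootstrap model selection across imputed data sets
#'
#' Runs the step-1 resampling of [bootstrap_select()] inside each completed
#' data set; by default qualification pools the inclusion fraction over all
#' `m * b_step1` step-1 models (`config$mi_qualify = "pooled"`), or
#' per-data-set with `"each"`. Step 2 then runs in each completed data set
#' and all `m * b_step2` compositions (2500 at the published defaults) are
#' pooled into one frequency table.
#'
#' @param imps An [impute()] result.
#' @param outcome Binary outcome name.
#' @param candidates Candidate predictor names.
#' @param config An [analysis_config()].
#' @param seed Integer seed.
#' @return A `stability_result` as in [bootstrap_select()], with pooled
#'   tables.
#' @export
mi_bootstrap_select <- function(imps, outcome, candidates,
                                config = analysis_config(), seed = 1L) {
  m <- imps$m
  canonical <- intersect(imps$completed[[1]]$spec$name, candidates)
  seeds <- split_seeds(seed, m, tag = 303L)
  if (m == 1L)
    return(bootstrap_select(imps$completed[[1]], outcome, candidates, config,
                            seed = seeds[1]))

  per <- vector("list", m)
  for (i in seq_len(m)) {
    ci <- imps$completed[[i]]
    dat <- ci$data[, c(outcome, candidates), drop = FALSE]
    y <- dat[[outcome]]
    dm <- design_matrix(dat, ci$spec, candidates)
    n <- nrow(dat)
    ss <- split_seeds(seeds[i], 2L, tag = 202L)
    set.seed(ss[1])
    s1 <- vector("list", config$b_step1)
    for (b in seq_len(config$b_step1)) {
      idx <- sample.int(n, n, replace = TRUE)
      s1[[b]] <- boot_replicate(dm$X, y, dm$blocks, candidates, ci$spec, dat,
                                config$alpha_univariable, config$alpha_backward,
                                canonical, screen = TRUE, idx = idx)
    }
    per[[i]] <- list(s1 = s1, dm = dm, y = y, n = n, seed2 = ss[2], spec = ci$spec,
                     dat = dat)
  }
  all_s1 <- unlist(lapply(per, `[[`, "s1"), recursive = FALSE)
  ok1 <- !vapply(all_s1, is.null, logical(1))
  failed1 <- sum(!ok1)
  incl_pooled <- inclusion_table(all_s1[ok1], candidates)

  qualified_for <- function(i) {
    if (config$mi_qualify == "pooled") {
      incl_pooled$predictor[incl_pooled$fraction >= config$inclusion_threshold]
    } else {
      s1i <- per[[i]]$s1
      oki <- !vapply(s1i, is.null, logical(1))
      ti <- inclusion_table(s1i[oki], candidates)
      ti$predictor[ti$fraction >= config$inclusion_threshold]
    }
  }

  comps <- list(); failed2 <- 0L
  union_qual <- character()
  for (i in seq_len(m)) {
    qual <- canonical_sort(qualified_for(i), canonical)
    union_qual <- union(union_qual, qual)
    if (length(qual) == 0L) next
    set.seed(per[[i]]$seed2)
    for (b in seq_len(config$b_step2)) {
      idx <- sample.int(per[[i]]$n, per[[i]]$n, replace = TRUE)
      r <- boot_replicate(per[[i]]$dm$X, per[[i]]$y, per[[i]]$dm$blocks, qual,
                          per[[i]]$spec, per[[i]]$dat,
                          config$alpha_univariable, config$alpha_backward,
                          canonical, screen = FALSE, idx = idx)
      if (is.null(r)) failed2 <- failed2 + 1L else comps[[length(comps) + 1L]] <- r
    }
  }
  if (length(union_qual) == 0L)
    warning("no predictor qualified after pooled bootstrap step 1", call. = FALSE)
  freq <- frequency_table(comps, canonical, failed = failed2)
  union_qual <- canonical_sort(union_qual, canonical)
  structure(list(step1_inclusion = incl_pooled, qualified = union_qual,
                 step2_frequencies = freq,
                 final_rank = if (length(union_qual))
                   rank_predictors(freq, union_qual, canonical)
                 else data.frame(predictor = character(), fraction = numeric(),
                                 rank = integer()),
                 failed_step1 = failed1, failed_step2 = failed2),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result>\n  qualified after step 1:",
      if (length(x$qualified)) paste(x$qualified, collapse = ", ") else "(none)",
      "\n")
  cat("  step 2:", attr(x$step2_frequencies, "total_models"), "models,",
      x$failed_step2, "failed replicates\n")
  print(x$step2_frequencies, top = 5L)
  invisible(x)
}
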