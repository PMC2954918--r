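# Orchestration of the four modelling strategies and rendering of the
# comparison tables: CCA (complete cases), MI (multiple imputation with
# inclusion-fraction pooling), B (two-step bootstrap on complete cases)
# and MI+B (the bootstrap inside each imputed data set).

#' Run one full modelling strategy
#'
#' Executes the chain screen -> (impute) -> select -> (stability) ->
#' validate for one of the four strategies, deterministically for a given
#' seed.
#'
#' * `"cca"`: complete cases, collinearity filter, univariable screen,
#'   backward elimination, optimism validation of the final model.
#' * `"mi"`: imputation, [mi_select()], pooled validation via
#'   [mi_performance()].
#' * `"b"`: complete cases, screen, [bootstrap_select()]; the most
#'   frequent step-2 composition is validated.
#' * `"mi_b"`: imputation, [mi_bootstrap_select()]; the most frequent
#'   pooled composition is validated with [mi_performance()].
#'
#' @param x A [cohort()].
#' @param outcome Binary outcome name.
#' @param candidates Candidate predictor names; defaults to all variables
#'   with role `"candidate"`.
#' @param config An [analysis_config()].
#' @param method One of `"cca"`, `"mi"`, `"b"`, `"mi_b"`.
#' @param seed Integer seed (defaults to `config$rng_seed`).
#' @return A list of class `strategy_bundle`: `method`, `screen`
#'   (collinearity drops, univariable drops, `epv`), `composition`,
#'   `model`/`models`, `stability` (for the bootstrap methods),
#'   `performance`, `seed`.
#' @export
run_strategy <- function(x, outcome, candidates = NULL,
                         config = analysis_config(),
                         method = c("cca", "mi", "b", "mi_b"),
                         seed = config$rng_seed) {
  method <- match.arg(method)
  spec <- x$spec
  if (is.null(candidates))
    candidates <- spec$name[spec$role == "candidate"]
  seeds <- split_seeds(seed, 4L, tag = 606L)

  screen_one <- function(cx) {
    col <- collinearity_filter(cx, candidates, config$collinearity_r)
    uni <- univariable_screen(cx, outcome, col$retained, config$alpha_univariable)
    epv <- tryCatch(
      suppressWarnings(events_per_variable(cx, outcome,
                                           max(length(uni$retained), 1L),
                                           config$epv_min)),
      error = function(e) NA_real_)
    list(collinear = col, univariable = uni, retained = uni$retained,
         epv = as.numeric(epv))
  }

  if (method %in% c("cca", "b")) {
    cc <- complete_cases(x, c(outcome, candidates))
    scr <- screen_one(cc)
    if (method == "cca") {
      sel <- if (length(scr$retained))
        backward_eliminate(cc, outcome, scr$retained, config$alpha_backward)
      else list(retained = character(),
                model = fit_logistic(cc, outcome), trace = NULL)
      perf <- validate_optimism(cc, outcome, sel$retained, config, seeds[1])
      bundle <- list(method = method, screen = scr,
                     composition = sel$retained, model = sel$model,
                     trace = sel$trace, stability = NULL, performance = perf,
                     excluded_fraction = attr(cc, "excluded_fraction"))
    } else {
      stab <- bootstrap_select(cc, outcome, scr$retained, config, seeds[2])
      comp <- top_composition(stab)
      perf <- validate_optimism(cc, outcome, comp, config, seeds[1])
      bundle <- list(method = method, screen = scr, composition = comp,
                     model = fit_logistic(cc, outcome, comp),
                     stability = stab, performance = perf,
                     excluded_fraction = attr(cc, "excluded_fraction"))
    }
  } else {
    imps <- impute(x, m = config$m_imputations, seed = seeds[3])
    scr <- screen_one(imps$completed[[1]])
    if (method == "mi") {
      sel <- mi_select(imps, outcome, scr$collinear$retained, config)
      perf <- mi_performance(imps, outcome, sel$confirmed, config, seeds[1])
      bundle <- list(method = method, screen = scr,
                     composition = sel$confirmed, models = sel$models,
                     pooled = if (length(sel$confirmed)) pool_rubin(sel$models),
                     selection = sel, stability = NULL, performance = perf)
    } else {
      stab <- mi_bootstrap_select(imps, outcome, scr$collinear$retained,
                                  config, seeds[2])
      comp <- top_composition(stab)
      perf <- mi_performance(imps, outcome, comp, config, seeds[1])
      bundle <- list(method = method, screen = scr, composition = comp,
                     models = lapply(imps$completed, fit_logistic,
                                     outcome = outcome, predictors = comp),
                     stability = stab, performance = perf)
    }
    bundle$imputations <- imps
  }
  bundle$outcome <- outcome
  bundle$seed <- seed
  class(bundle) <- "strategy_bundle"
  bundle
}

# The most frequently selected composition of a stability result.
top_composition <- function(stab) {
  freq <- stab$step2_frequencies
  if (nrow(freq) == 0L) return(character())
  key <- freq$composition[1]
  if (key == "(intercept only)") character() else
    strsplit(key, " + ", fixed = TRUE)[[1]]
}

#' @export
print.strategy_bundle <- function(x, ...) {
  cat("<strategy_bundle> method =", x$method, "\n")
  cat("  composition:", if (length(x$composition))
    paste(x$composition, collapse = ", ") else "(intercept only)", "\n")
  cat(sprintf("  apparent c = %.3f, corrected c = %.3f\n",
              x$performance$apparent_c, x$performance$corrected_c))
  invisible(x)
}

#' Render a top-k model-selection frequency table
#'
#' Lays out the `top` most frequently selected compositions as a
#' predictor-by-model X/- grid followed by `Count` and `%` rows (percent
#' printed to one decimal of the step-2 model total).
#'
#' @param freq A [frequency_table()].
#' @param top Number of compositions to show (default 5).
#' @return A character matrix; attribute `percent` holds the numeric
#'   percent row.
#' @export
render_frequency_table <- function(freq, top = 5L) {
  total <- attr(freq, "total_models")
  k <- min(top, nrow(freq))
  if (k == 0L)
    return(structure(matrix(character(), 0, 0), percent = numeric()))
  sets <- strsplit(freq$composition[seq_len(k)], " + ", fixed = TRUE)
  sets[freq$composition[seq_len(k)] == "(intercept only)"] <- list(character())
  preds <- unique(unlist(sets))
  grid <- vapply(seq_len(k), function(j)
    ifelse(preds %in% sets[[j]], "X", "-"), character(length(preds)))
  if (length(preds) == 1L) grid <- matrix(grid, nrow = 1)
  pct <- 100 * freq$count[seq_len(k)] / total
  out <- rbind(grid,
               Count = as.character(freq$count[seq_len(k)]),
               `%` = sprintf("%.1f", pct))
  rownames(out) <- c(preds, "Count", "%")
  colnames(out) <- as.character(seq_len(k))
  structure(out, percent = round(pct, 1))
}

#' Render a performance comparison grid
#'
#' One column per strategy bundle, rows: calibration slope, Nagelkerke
#' R-squared, apparent c with its 95\% CI, optimism, corrected c.
#'
#' @param bundles A list of `strategy_bundle`s.
#' @param digits Rounding for display (default 3).
#' @return A data frame with one row per performance measure.
#' @export
render_performance_grid <- function(bundles, digits = 3) {
  stopifnot(length(bundles) >= 1)
  cols <- lapply(bundles, function(b) {
    p <- b$performance
    c(`calibration slope` = sprintf("%.*f", digits, p$calibration_slope),
      `R2 (Nagelkerke)` = sprintf("%.*f", digits, p$r2_nagelkerke),
      `apparent c (95% CI)` = sprintf("%.*f (%.*f, %.*f)", digits, p$apparent_c,
                                      digits, p$c_ci_low, digits, p$c_ci_high),
      optimism = sprintf("%.*f", digits, p$optimism),
      `corrected c` = sprintf("%.*f", digits, p$corrected_c))
  })
  out <- as.data.frame(cols, check.names = FALSE)
  names(out) <- toupper(vapply(bundles, `[[`, character(1), "method"))
  cbind(measure = rownames(out), `rownames<-`(out, NULL))
}

#' Render a composition-rank comparison across strategies
#'
#' Predictors of every bundle's final composition, ranked within each
#' strategy by absolute standardized coefficient (largest first), so
#' predictors on different measurement scales are comparable.
#'
#' @param bundles A list of `strategy_bundle`s.
#' @param x The [cohort()] the bundles were derived from (for predictor
#'   standard deviations).
#' @return A data frame, one row per predictor appearing anywhere, one
#'   rank column per strategy (`NA` = not selected).
#' @export
render_composition_table <- function(bundles, x) {
  all_preds <- unique(unlist(lapply(bundles, `[[`, "composition")))
  all_preds <- canonical_sort(all_preds, x$spec$name)
  out <- data.frame(predictor = all_preds, stringsAsFactors = FALSE)
  for (b in bundles) {
    mo <- if (!is.null(b$model)) b$model else b$models[[1]]
    ranks <- rep(NA_integer_, length(all_preds))
    if (length(b$composition)) {
      sc <- vapply(b$composition, function(v) {
        ix <- mo$blocks[[v]] - 1L  # coefficient positions
        cf <- mo$coefficients[ix]
        s <- stats::sd(x$data[[v]], na.rm = TRUE)
        max(abs(cf * s), na.rm = TRUE)
      }, numeric(1))
      ord <- b$composition[order(-sc)]
      ranks[match(ord, all_preds)] <- seq_along(ord)
    }
    out[[toupper(b$method)]] <- ranks
  }
  out
}

#' Serialize a strategy bundle to JSON
#'
#' @param bundle A `strategy_bundle`.
#' @param path Output file.
#' @export
write_bundle_json <- function(bundle, path) {
  perf <- bundle$performance
  obj <- list(method = bundle$method,
              seed = bundle$seed,
              composition = bundle$composition,
              epv = bundle$screen$epv,
              performance = perf[c("apparent_c", "c_ci_low", "c_ci_high",
                                   "calibration_slope", "r2_nagelkerke",
                                   "optimism", "corrected_c")])
  if (!is.null(bundle$stability)) {
    st <- bundle$stability
    obj$stability <- list(
      qualified = st$qualified,
      total_models = attr(st$step2_frequencies, "total_models"),
      failed_replicates = st$failed_step2,
      top = utils::head(as.data.frame(st$step2_frequencies), 10))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
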