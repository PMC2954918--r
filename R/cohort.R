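#' Declare a study variable
#'
#' A variable specification records everything the modelling chain needs to
#' know about one column of a cohort table: its role in the analysis, its
#' measurement level, the ordered label set for categorical variables, and a
#' clinical-priority rank used by the collinearity filter (rank 1 = easiest
#' to obtain in clinical practice, and therefore preferred when two
#' correlated predictors compete).
#'
#' @param name Column name (must match the CSV header).
#' @param role One of `"outcome_raw"`, `"candidate"`, `"auxiliary"`,
#'   `"criterion"`, `"id"`.
#' @param measurement One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param levels Ordered character vector of labels; required for
#'   categorical variables. Codes `1..k` follow this declared order so that
#'   category coding is stable across files, imputations and resamples.
#' @param clinical_priority Positive integer rank; required for candidates
#'   that may enter the collinearity filter. Lower = retained preferentially.
#' @return A one-row data frame of class `var_spec`.
#' @seealso [cohort_spec()], [read_cohort()]
#' @export
var_spec <- function(name, role = "candidate", measurement = "continuous",
                     levels = NULL, clinical_priority = NA_integer_) {
  role <- match.arg(role, c("outcome_raw", "candidate", "auxiliary", "criterion", "id"))
  measurement <- match.arg(measurement, c("continuous", "binary", "categorical"))
  if (measurement == "categorical") {
    if (is.null(levels) || length(levels) < 2L)
      stop("categorical variable '", name, "' needs >= 2 declared levels", call. = FALSE)
  } else if (!is.null(levels) && measurement == "continuous") {
    stop("levels are only meaningful for binary/categorical variables", call. = FALSE)
  }
  out <- data.frame(name = as.character(name), role = role,
                    measurement = measurement,
                    clinical_priority = as.integer(clinical_priority),
                    stringsAsFactors = FALSE)
  out$levels <- list(if (is.null(levels)) character() else as.character(levels))
  class(out) <- c("var_spec", class(out))
  out
}

#' Assemble and validate a full cohort specification
#'
#' @param ... `var_spec` rows (or data frames of them).
#' @return A data frame of class `cohort_spec`, one row per variable.
#' @export
cohort_spec <- function(...) {
  specs <- list(...)
  spec <- do.call(rbind, lapply(specs, function(s) { class(s) <- "data.frame"; s }))
  if (anyDuplicated(spec$name))
    stop("duplicate variable names in spec", call. = FALSE)
  if (sum(spec$role == "outcome_raw") > 1L)
    stop("at most one variable may have role 'outcome_raw'", call. = FALSE)
  pri <- spec$clinical_priority[spec$role == "candidate" & !is.na(spec$clinical_priority)]
  if (anyDuplicated(pri))
    stop("clinical_priority ranks must be unique among candidates", call. = FALSE)
  class(spec) <- c("cohort_spec", "data.frame")
  spec
}

spec_row <- function(spec, name) {
  i <- match(name, spec$name)
  if (is.na(i)) stop("variable '", name, "' not in spec", call. = FALSE)
  spec[i, , drop = FALSE]
}

n_levels <- function(spec, name) length(spec$levels[[match(name, spec$name)]])

#' Construct a cohort table
#'
#' A cohort is a subject-by-variable rectangle with one row per subject and
#' one numeric column per declared variable. Missing cells are `NA`; the
#' explicit missingness mask is available via [missing_mask()]. Binary
#' variables hold 0/1; categorical variables hold integer codes `1..k` in
#' declared level order.
#'
#' @param data A data frame with exactly the spec's columns.
#' @param spec A [cohort_spec()].
#' @return An object of class `cohort`: a list with elements `data` and
#'   `spec`.
#' @export
cohort <- function(data, spec) {
  if (!all(spec$name %in% names(data)))
    stop("data is missing spec'd column(s): ",
         paste(setdiff(spec$name, names(data)), collapse = ", "), call. = FALSE)
  data <- as.data.frame(data)[, spec$name, drop = FALSE]
  if (nrow(data) < 1L) stop("cohort must have at least one subject", call. = FALSE)
  for (i in seq_len(nrow(spec))) {
    v <- spec$name[i]
    x <- data[[v]]
    if (is.logical(x) && all(is.na(x))) x <- as.numeric(x)
    if (!is.numeric(x))
      stop("column '", v, "' is not numeric; use read_cohort() for label mapping",
           call. = FALSE)
    obs <- x[!is.na(x)]
    if (spec$measurement[i] == "binary" && length(obs) && !all(obs %in% c(0, 1)))
      stop("binary column '", v, "' has values outside {0,1}", call. = FALSE)
    if (spec$measurement[i] == "categorical") {
      k <- length(spec$levels[[i]])
      if (length(obs) && !all(obs %in% seq_len(k)))
        stop("categorical column '", v, "' has codes outside 1..", k, call. = FALSE)
    }
    if (all(is.na(x)))
      stop("column '", v, "' is entirely missing", call. = FALSE)
    data[[v]] <- as.double(x)  # uniform storage so round-trips are exact
  }
  structure(list(data = data, spec = spec), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$data), " subjects x ", ncol(x$data), " variables; ",
      sum(is.na(x$data)), " missing cells (",
      sprintf("%.1f%%", 100 * mean(is.na(as.matrix(x$data)))), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$data)

#' Explicit missingness mask
#'
#' @param x A [cohort()].
#' @return An n-by-p logical matrix, `TRUE` exactly where a cell is missing.
#' @export
missing_mask <- function(x) {
  m <- is.na(as.matrix(x$data))
  dimnames(m) <- list(NULL, names(x$data))
  m
}

#' Read a cohort from CSV
#'
#' Reads an RFC-4180 CSV with a header row, maps missing-value tokens to the
#' mask and declared categorical labels to stable integer codes (declared
#' level order, not file order).
#'
#' @param path CSV file path.
#' @param spec A [cohort_spec()]; every spec'd name must appear in the header.
#' @param missing_tokens Tokens treated as missing. Default `c("", "NA")`.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, spec, missing_tokens = c("", "NA")) {
  if (length(missing_tokens) == 0L) stop("missing_tokens must be non-empty", call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  missing_cols <- setdiff(spec$name, names(raw))
  if (length(missing_cols))
    stop("CSV header lacks spec'd column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(spec)), function(i) {
    v <- spec$name[i]
    tok <- trimws(raw[[v]])
    x <- rep(NA_real_, length(tok))
    miss <- tok %in% missing_tokens
    lv <- spec$levels[[i]]
    if (length(lv) && spec$measurement[i] != "continuous") {
      # declared labels map to stable codes; numeric tokens pass through
      code <- match(tok, lv)
      if (spec$measurement[i] == "binary") code <- code - 1
      num <- suppressWarnings(as.numeric(tok))
      x[!miss] <- ifelse(!is.na(code[!miss]), code[!miss], num[!miss])
    } else {
      x[!miss] <- suppressWarnings(as.numeric(tok[!miss]))
    }
    bad <- which(!miss & is.na(x))
    if (length(bad))
      stop("cannot parse value '", tok[bad[1]], "' at row ", bad[1],
           ", column '", v, "'", call. = FALSE)
    x
  })
  names(out) <- spec$name
  cohort(as.data.frame(out, check.names = FALSE), spec)
}

#' Write a cohort to CSV
#'
#' Non-missing cells round-trip bit-identically through [read_cohort()];
#' missing cells are written as the empty token. Categorical codes are
#' written as their declared labels.
#'
#' @param x A [cohort()].
#' @param path Output path.
#' @export
write_cohort <- function(x, path) {
  spec <- x$spec
  cols <- lapply(seq_len(nrow(spec)), function(i) {
    v <- spec$name[i]
    val <- x$data[[v]]
    lv <- spec$levels[[i]]
    out <- character(length(val))
    obs <- !is.na(val)
    if (spec$measurement[i] == "categorical" && length(lv)) {
      out[obs] <- lv[val[obs]]
    } else {
      out[obs] <- sprintf("%.17g", val[obs])
    }
    out
  })
  names(cols) <- spec$name
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a cohort to complete cases
#'
#' Drops every subject with a missing value on any of the selected columns —
#' the complete-case analysis (CCA) input. The excluded fraction is attached
#' as attribute `excluded_fraction`.
#'
#' @param x A [cohort()].
#' @param columns Column names to require complete; defaults to all.
#' @return A [cohort()] with attribute `excluded_fraction`.
#' @export
complete_cases <- function(x, columns = names(x$data)) {
  bad <- setdiff(columns, names(x$data))
  if (length(bad)) stop("unknown column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  keep <- stats::complete.cases(x$data[, columns, drop = FALSE])
  if (!any(keep)) stop("no complete cases remain on the selected columns", call. = FALSE)
  out <- cohort(x$data[keep, , drop = FALSE], x$spec)
  attr(out, "excluded_fraction") <- 1 - mean(keep)
  out
}

#' Analysis configuration
#'
#' Bundles the tuning constants of the whole modelling chain. Defaults
#' follow the published strategy this package implements: univariable
#' pre-selection and backward elimination both stop at alpha = 0.157
#' (comparable to AIC-based selection), five imputations, 500 + 500
#' two-step bootstrap resamples, a 40\% inclusion-fraction threshold, 200
#' validation resamples, a Pearson r >= 0.5 collinearity trigger and an
#' events-per-variable floor of 10.
#'
#' @param alpha_univariable,alpha_backward,alpha_lrt Significance levels for
#'   the univariable screen, the backward-elimination stopping rule, and the
#'   pooled likelihood-ratio confirmation.
#' @param m_imputations Number of imputed data sets.
#' @param b_step1,b_step2 Bootstrap resample counts for the two selection
#'   steps.
#' @param inclusion_threshold Inclusion fraction needed to qualify.
#' @param b_validation Bootstrap resamples for optimism estimation.
#' @param collinearity_r Absolute Pearson correlation that triggers the
#'   collinearity filter.
#' @param epv_min Events-per-variable power floor.
#' @param rng_seed Master seed recorded with results.
#' @param mi_qualify `"pooled"` pools step-1 inclusion over all imputations;
#'   `"each"` qualifies per imputed data set.
#' @param lrt_pool `"D2"` pools likelihood-ratio statistics across
#'   imputations with an average-relative-increase correction and an F
#'   reference; `"median_p"` is a simpler cross-checking fallback.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(alpha_univariable = 0.157,
                            alpha_backward = 0.157,
                            alpha_lrt = 0.157,
                            m_imputations = 5L,
                            b_step1 = 500L,
                            b_step2 = 500L,
                            inclusion_threshold = 0.40,
                            b_validation = 200L,
                            collinearity_r = 0.5,
                            epv_min = 10,
                            rng_seed = 1L,
                            mi_qualify = c("pooled", "each"),
                            lrt_pool = c("D2", "median_p")) {
  cfg <- list(alpha_univariable = alpha_univariable,
              alpha_backward = alpha_backward,
              alpha_lrt = alpha_lrt,
              m_imputations = as.integer(m_imputations),
              b_step1 = as.integer(b_step1),
              b_step2 = as.integer(b_step2),
              inclusion_threshold = inclusion_threshold,
              b_validation = as.integer(b_validation),
              collinearity_r = collinearity_r,
              epv_min = epv_min,
              rng_seed = as.integer(rng_seed),
              mi_qualify = match.arg(mi_qualify),
              lrt_pool = match.arg(lrt_pool))
  fr <- c("alpha_univariable", "alpha_backward", "alpha_lrt",
          "inclusion_threshold", "collinearity_r")
  for (f in fr)
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop(f, " must lie in (0,1)", call. = FALSE)
  for (f in c("m_imputations", "b_step1", "b_step2", "b_validation"))
    if (cfg[[f]] < 1L) stop(f, " must be >= 1", call. = FALSE)
  class(cfg) <- "analysis_config"
  cfg
}
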