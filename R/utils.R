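# Internal helpers shared across modules.

# Derive `n` reproducible sub-seeds from a master seed. Used to give
# independent random streams to imputations, bootstrap step 1 / step 2,
# and validation resampling.
split_seeds <- function(seed, n, tag = 0L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  set.seed(as.integer((as.numeric(seed) + 7919 * tag) %% 2147483646) + 1L)
  sample.int(2147483646L, n)
}

# Canonical ordering of predictor names: the order in which candidates are
# declared in the cohort spec. Makes model compositions, tie-breaks and
# frequency tables invariant to the order callers pass predictors in.
canonical_sort <- function(names, canonical) {
  names[order(match(names, canonical))]
}

composition_key <- function(predictors, canonical) {
  if (length(predictors) == 0L) return("(intercept only)")
  paste(canonical_sort(predictors, canonical), collapse = " + ")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
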