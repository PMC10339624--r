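# internal helpers shared across modules

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) stats::plogis(x)

#' @importFrom rlang abort warn
NULL

# Deterministic per-run seed derivation. A master seed spawns independent
# substreams so that growing the number of runs never reshuffles earlier
# runs. `stream` separates logically distinct uses (subsampling vs
# permutation) under the same master seed. Kept below 2^31 - 1.
derive_seed <- function(seed, run, stream = 0L) {
  s <- (as.double(seed) %% 2147483647) * 69069 +
    as.double(run) * 1000003 + as.double(stream) * 7919
  as.integer(s %% 2147483646) + 1L
}

assert_beta_matrix <- function(X, arg = "X") {
  if (!is.matrix(X) || !is.numeric(X)) {
    abort(sprintf("`%s` must be a numeric matrix (samples x CpGs)", arg))
  }
  if (is.null(colnames(X))) {
    abort(sprintf("`%s` must have CpG ids as column names", arg))
  }
  if (anyNA(X)) abort(sprintf("`%s` contains missing values", arg))
  invisible(X)
}

assert_response <- function(y, n, arg = "y") {
  if (!is.numeric(y) || length(y) != n) {
    abort(sprintf("`%s` must be a numeric vector of length %d", arg, n))
  }
  if (any(!is.finite(y))) abort(sprintf("`%s` contains non-finite values", arg))
  invisible(y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
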