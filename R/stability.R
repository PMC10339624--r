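#' Choose the lasso penalty by cross-validation
#'
#' Ten-fold (by default) cross-validation of the lasso on the full data,
#' returning the penalty that minimises mean cross-validated squared error
#' (the `lambda.min` convention). Fold assignment is drawn from the seed,
#' so the choice is reproducible.
#'
#' @param X Numeric matrix, samples x CpGs, with CpG ids as column names.
#' @param y Gestational age in days, one value per row of `X`.
#' @param folds Number of CV folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @return The chosen penalty (a single number).
#' @export
choose_lambda_cv <- function(X, y, folds = 10, seed = 1L) {
  assert_beta_matrix(X)
  assert_response(y, nrow(X))
  if (folds < 2) abort("folds must be >= 2")
  if (nrow(X) < folds) abort("need at least as many samples as folds")
  if (stats::sd(y) == 0) abort("y is constant; nothing to tune against")
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = nrow(X)))
  cv <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = foldid,
                          standardize = TRUE)
  cv$lambda.min
}

#' Fit a lasso at a fixed penalty and return the selected CpGs
#'
#' Minimises `1/2 * mean squared error + lam * sum(|coef|)` with an
#' unpenalised intercept; features are standardised to unit variance before
#' fitting (coefficients are reported on the original scale). A feature is
#' "selected" when its coefficient is nonzero beyond a numerical floor at
#' the solver's convergence tolerance. Zero-variance features are never
#' selected.
#'
#' @param X Numeric matrix, samples x features (column names = feature ids).
#' @param y Response vector.
#' @param lam Penalty value, >= 0.
#' @param standardize Standardise features within the fit (default TRUE).
#' @return Character vector of selected feature ids (possibly empty).
#' @export
fit_lasso <- function(X, y, lam, standardize = TRUE) {
  assert_beta_matrix(X)
  assert_response(y, nrow(X))
  if (lam < 0) abort("lam must be >= 0")
  if (ncol(X) == 1L) {
    # closed-form 1-D solution (glmnet needs >= 2 columns): with intercept,
    # b = soft(mean(xc * yc), lam) / mean(xc^2), on the standardized scale
    # when standardize is on
    x <- X[, 1]
    n <- length(x)
    v <- mean((x - mean(x))^2)
    if (v == 0) return(character(0))
    xc <- if (standardize) (x - mean(x)) / sqrt(v) else x - mean(x)
    yc <- y - mean(y)
    rho <- mean(xc * yc)
    denom <- mean(xc^2)
    b <- sign(rho) * max(abs(rho) - lam, 0) / denom
    return(if (abs(b) > 1e-12) colnames(X) else character(0))
  }
  # tight tolerance so the active set is the unique optimum's, independent
  # of coordinate order
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lam,
                        standardize = standardize, thresh = 1e-12,
                        maxit = 1e6)
  b <- as.numeric(fit$beta)
  colnames(X)[abs(b) > 1e-12]
}

#' Stability-selection configuration
#'
#' @param n_subsamples Number of subsample runs `B` (default 1000; reduced
#'   instances commonly use 100).
#' @param subsample_size Samples per run; default `floor(n/2)`, resolved at
#'   run time when `NULL`.
#' @param cv_folds Folds for [choose_lambda_cv()] when the penalty is tuned.
#' @param standardize Standardise features within every subsample fit.
#' @param permutation One fresh permutation of the response per run
#'   (`"per_run"`, default) or a single global permutation (`"global"`) in
#'   [estimate_q_permutation()].
#' @param seed Master seed; independent per-run substreams are derived from
#'   it so changing `n_subsamples` never reshuffles earlier runs.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(n_subsamples = 1000,
                             subsample_size = NULL,
                             cv_folds = 10,
                             standardize = TRUE,
                             permutation = c("per_run", "global"),
                             seed = 1L) {
  if (n_subsamples < 1) abort("n_subsamples must be >= 1")
  structure(
    list(
      n_subsamples = as.integer(n_subsamples),
      subsample_size = if (!is.null(subsample_size)) as.integer(subsample_size),
      cv_folds = as.integer(cv_folds),
      standardize = isTRUE(standardize),
      permutation = match.arg(permutation),
      seed = as.integer(seed)
    ),
    class = "selection_config"
  )
}

resolve_subsample_size <- function(config, n) {
  m <- config$subsample_size %||% (n %/% 2L)
  if (m < 1 || m >= n) abort("subsample_size must satisfy 1 <= size < n")
  m
}

#' Run stability selection
#'
#' Repeats the lasso at a fixed penalty on `B` random half-subsamples
#' (drawn without replacement) and records, for every CpG, the proportion
#' of runs in which it received a nonzero coefficient — its selection
#' probability.
#'
#' @param X Numeric matrix, samples x CpGs.
#' @param y Gestational age in days.
#' @param lam Fixed lasso penalty (tune beforehand with
#'   [choose_lambda_cv()]).
#' @param config A [selection_config()].
#' @return A tibble of class `selection_profile` with columns `cpg_id`,
#'   `selection_count`, `selection_probability`, carrying attributes `B`,
#'   `lam_used`, and `runs` — the per-run log (run index, seed, number
#'   selected, and the selected ids) from which the profile can be
#'   recomputed exactly.
#' @export
run_stability_selection <- function(X, y, lam, config = selection_config()) {
  assert_beta_matrix(X)
  assert_response(y, nrow(X))
  n <- nrow(X)
  m <- resolve_subsample_size(config, n)
  B <- config$n_subsamples

  counts <- integer(ncol(X))
  names(counts) <- colnames(X)
  run_seeds <- integer(B)
  n_selected <- integer(B)
  selected <- vector("list", B)

  for (b in seq_len(B)) {
    run_seeds[b] <- derive_seed(config$seed, b, stream = 0L)
    set.seed(run_seeds[b])
    idx <- sample.int(n, m)
    sel <- fit_lasso(X[idx, , drop = FALSE], y[idx], lam,
                     standardize = config$standardize)
    counts[sel] <- counts[sel] + 1L
    n_selected[b] <- length(sel)
    selected[[b]] <- sel
  }

  profile <- tibble::tibble(
    cpg_id = colnames(X),
    selection_count = unname(counts),
    selection_probability = unname(counts) / B
  )
  structure(
    profile,
    B = B,
    lam_used = lam,
    runs = tibble::tibble(run = seq_len(B), seed = run_seeds,
                          n_selected = n_selected, selected = selected),
    class = c("selection_profile", class(profile))
  )
}

#' Estimate the average selected-set size under a permuted response
#'
#' Calibrates `q` — the average number of features the lasso selects per
#' subsample run when the response carries no signal — by rerunning the
#' subsampled lasso with permuted gestational ages. By default each run
#' permutes `y` afresh; a single global permutation is available via the
#' config.
#'
#' @inheritParams run_stability_selection
#' @return The mean per-run selected count (a single number), with
#'   attribute `runs` holding the per-run log.
#' @export
estimate_q_permutation <- function(X, y, lam, config = selection_config()) {
  assert_beta_matrix(X)
  assert_response(y, nrow(X))
  n <- nrow(X)
  m <- resolve_subsample_size(config, n)
  B <- config$n_subsamples

  if (config$permutation == "global") {
    set.seed(derive_seed(config$seed, 0L, stream = 1L))
    y_global <- sample(y)
  }

  run_seeds <- integer(B)
  n_selected <- integer(B)
  for (b in seq_len(B)) {
    run_seeds[b] <- derive_seed(config$seed, b, stream = 1L)
    set.seed(run_seeds[b])
    y_b <- if (config$permutation == "per_run") sample(y) else y_global
    idx <- sample.int(n, m)
    sel <- fit_lasso(X[idx, , drop = FALSE], y_b[idx], lam,
                     standardize = config$standardize)
    n_selected[b] <- length(sel)
  }

  structure(
    mean(n_selected),
    runs = tibble::tibble(run = seq_len(B), seed = run_seeds,
                          n_selected = n_selected)
  )
}

#' Selection-probability threshold from a false-discovery budget
#'
#' Inverts the stability-selection false-discovery bound
#' \deqn{E(V) \le \frac{q^2}{(2\pi_{thr} - 1)\,p}}
#' for the threshold: \eqn{\pi_{thr} = \min(1, (1 + q^2/(E(V)\,p))/2)},
#' the smallest selection-probability cutoff at which the expected number
#' of false discoveries among features passing it is bounded by `E_V`.
#' Here `q` is the average number of features selected per subsample run
#' (estimated under outcome permutation by [estimate_q_permutation()]) and
#' `p` the total number of features. When `q^2 > E_V * p`, no threshold
#' below 1 attains the budget and the capped value 1 is returned with a
#' warning.
#'
#' @param E_V Expected-false-discovery bound value (> 0).
#' @param q Average selected-set size per run (>= 0).
#' @param p Total number of features (>= 1).
#' @return A list of class `fd_bound`: `E_V`, `q`, `p`, `pi_thr`.
#' @export
#' @examples
#' compute_threshold(E_V = 1, q = 593.8, p = 769139)$pi_thr # ~0.729
compute_threshold <- function(E_V, q, p) {
  if (E_V <= 0) abort("E_V must be > 0")
  if (q < 0) abort("q must be >= 0")
  if (p < 1) abort("p must be >= 1")
  pi_raw <- (1 + q^2 / (E_V * p)) / 2
  if (pi_raw > 1) {
    warn(sprintf(
      "false-discovery bound %.3g unattainable below probability 1 (q^2/p = %.3g); threshold capped at 1",
      E_V, q^2 / p
    ))
    pi_thr <- 1
  } else {
    pi_thr <- pi_raw
  }
  structure(list(E_V = E_V, q = q, p = p, pi_thr = pi_thr),
            class = "fd_bound")
}

#' @export
print.fd_bound <- function(x, ...) {
  cat(sprintf(
    "<fd_bound> E(V) <= %.4g at pi_thr = %.4f  (q = %.4g, p = %d)\n",
    x$E_V, x$pi_thr, x$q, as.integer(x$p)
  ))
  invisible(x)
}

# the bound evaluated at a threshold: E(V) <= q^2 / ((2 pi - 1) p)
fd_bound_value <- function(pi_thr, q, p) q^2 / ((2 * pi_thr - 1) * p)

#' Features passing the stability threshold
#'
#' @param profile A `selection_profile` from [run_stability_selection()].
#' @param pi_thr Threshold in (0.5, 1], or an `fd_bound` from
#'   [compute_threshold()].
#' @return Tibble of stable features (`cpg_id`, `selection_count`,
#'   `selection_probability`), probability descending, ties broken by
#'   `cpg_id` ascending. Inclusion is at `>= pi_thr`.
#' @export
stable_features <- function(profile, pi_thr) {
  if (inherits(pi_thr, "fd_bound")) pi_thr <- pi_thr$pi_thr
  if (pi_thr <= 0.5 || pi_thr > 1) abort("pi_thr must be in (0.5, 1]")
  profile |>
    dplyr::filter(.data$selection_probability >= pi_thr) |>
    dplyr::arrange(dplyr::desc(.data$selection_probability), .data$cpg_id) |>
    tibble::as_tibble()
}

#' @export
tidy.selection_profile <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.selection_profile <- function(x, ...) {
  runs <- attr(x, "runs")
  tibble::tibble(
    n_cpgs = nrow(x),
    B = attr(x, "B"),
    lam_used = attr(x, "lam_used"),
    mean_selected_per_run = mean(runs$n_selected),
    max_probability = max(x$selection_probability)
  )
}
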