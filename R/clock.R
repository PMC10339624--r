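#' Split a cohort into training and test sets
#'
#' Seed-reproducible random partition. The test set gets
#' `round(n * (1 - train_fraction))` samples and the training set the rest,
#' so the two are disjoint and exhaustive.
#'
#' @param cohort A `dnam_cohort` from [generate_cohort()], or any list with
#'   a `betas` matrix and a `samples` tibble.
#' @param train_fraction Fraction of samples assigned to training, in (0,1).
#' @param seed Integer seed for the partition.
#' @return List with `train` and `test`, each a `dnam_cohort`-shaped list.
#' @export
split_train_test <- function(cohort, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)")
  }
  n <- nrow(cohort$betas)
  if (n < 10) abort("need at least 10 samples to split")
  n_test <- round(n * (1 - train_fraction))
  set.seed(seed)
  test_idx <- sort(sample.int(n, n_test))
  subset_cohort <- function(idx) {
    structure(
      list(
        betas = cohort$betas[idx, , drop = FALSE],
        samples = cohort$samples[idx, ],
        truth = cohort$truth,
        config = cohort$config
      ),
      class = "dnam_cohort"
    )
  }
  list(train = subset_cohort(setdiff(seq_len(n), test_idx)),
       test = subset_cohort(test_idx))
}

#' Univariate GAM of gestational age on one CpG
#'
#' Fits a penalized cubic regression spline of GA on a single CpG's beta
#' values, with the penalty level chosen by generalized cross-validation
#' (or REML). The smooth's effective degrees of freedom (EDF) serve as a
#' nonlinearity diagnostic: EDF near 1 means the fitted relationship is
#' effectively linear, larger EDF means genuine curvature survived the
#' penalty.
#'
#' @param x One CpG's beta values.
#' @param y Gestational age in days.
#' @param basis_dim Spline basis dimension (default 10, accommodating
#'   strongly nonlinear DNAm--GA relationships).
#' @param method Penalty-selection criterion, `"GCV.Cp"` (default) or
#'   `"REML"`.
#' @param cpg_id Optional feature id carried into the result.
#' @return A list of class `gam_fit`: `cpg_id`, `r2` (training variance
#'   explained), `edf`, `basis_dim`, and the underlying `mgcv` fit.
#' @export
fit_univariate_gam <- function(x, y, basis_dim = 10,
                               method = c("GCV.Cp", "REML"),
                               cpg_id = NULL) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (stats::sd(x) == 0) abort("x is constant; cannot fit a smooth")
  if (length(x) <= basis_dim) {
    abort(sprintf("n = %d too small for basis_dim = %d; reduce basis_dim",
                  length(x), basis_dim))
  }
  d <- data.frame(y = y, x = x)
  fit <- mgcv::gam(y ~ s(x, bs = "cr", k = basis_dim), data = d,
                   method = method)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  # EDF of the spline term alone (intercept excluded): 1 <=> linear
  edf <- sum(fit$edf) - 1
  structure(
    list(cpg_id = cpg_id %||% NA_character_,
         r2 = r2,
         edf = edf,
         basis_dim = basis_dim,
         fit = fit),
    class = "gam_fit"
  )
}

#' Screen CpGs by univariate GAM fit
#'
#' Convenience wrapper fitting [fit_univariate_gam()] to each listed CpG
#' and collecting training R-squared and EDF in one tibble.
#'
#' @param X Beta matrix, samples x CpGs.
#' @param y Gestational age in days.
#' @param cpg_ids CpGs to screen (default: all columns of `X`).
#' @inheritParams fit_univariate_gam
#' @return Tibble: `cpg_id`, `r2`, `edf`.
#' @export
screen_cpgs <- function(X, y, cpg_ids = colnames(X), basis_dim = 10,
                        method = c("GCV.Cp", "REML")) {
  method <- match.arg(method)
  assert_beta_matrix(X)
  missing <- setdiff(cpg_ids, colnames(X))
  if (length(missing)) {
    abort(sprintf("CpGs not in matrix: %s", paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(cpg_ids, function(id) {
    f <- fit_univariate_gam(X[, id], y, basis_dim = basis_dim,
                            method = method, cpg_id = id)
    tibble::tibble(cpg_id = id, r2 = f$r2, edf = f$edf)
  })
}

#' Order CpGs by univariate fit
#'
#' @param fits A tibble with `cpg_id` and `r2` columns (e.g. from
#'   [screen_cpgs()]), or a list of `gam_fit` objects.
#' @return Character vector of CpG ids, descending R-squared, ties broken
#'   by id ascending.
#' @export
rank_by_r2 <- function(fits) {
  if (!is.data.frame(fits)) {
    fits <- purrr::map_dfr(fits, function(f) {
      tibble::tibble(cpg_id = f$cpg_id, r2 = f$r2)
    })
  }
  if (nrow(fits) == 0) abort("no fits to rank")
  fits |>
    dplyr::arrange(dplyr::desc(.data$r2), .data$cpg_id) |>
    dplyr::pull("cpg_id")
}

#' Build nested GAM clocks of increasing size
#'
#' Model `k` regresses GA on penalized cubic-spline smooths of the top-`k`
#' ranked CpGs (one smooth per CpG plus an intercept); every model
#' re-selects its smoothing penalties independently.
#'
#' @param X_train Training beta matrix, samples x CpGs (rownames = sample
#'   ids, used for train/test leakage checks at evaluation).
#' @param y_train Training GA in days.
#' @param ranked_ids CpGs in the order produced by [rank_by_r2()].
#' @param k_max Largest clock size; clocks are built for k = 1..k_max.
#' @inheritParams fit_univariate_gam
#' @return List of `ga_clock` objects, element k holding the k-CpG clock.
#' @export
build_nested_clocks <- function(X_train, y_train, ranked_ids, k_max,
                                basis_dim = 10,
                                method = c("GCV.Cp", "REML")) {
  method <- match.arg(method)
  assert_beta_matrix(X_train)
  assert_response(y_train, nrow(X_train))
  if (k_max < 1) abort("k_max must be >= 1")
  if (length(ranked_ids) < k_max) {
    abort(sprintf("ranking has %d CpGs but k_max = %d",
                  length(ranked_ids), k_max))
  }
  purrr::map(seq_len(k_max), function(k) {
    fit_gam_clock(X_train, y_train, ranked_ids[seq_len(k)],
                  basis_dim = basis_dim, method = method)
  })
}

fit_gam_clock <- function(X_train, y_train, cpg_ids, basis_dim = 10,
                          method = "GCV.Cp") {
  d <- as.data.frame(X_train[, cpg_ids, drop = FALSE])
  d$.ga <- y_train
  terms <- sprintf("s(%s, bs = \"cr\", k = %d)", cpg_ids, basis_dim)
  form <- stats::as.formula(paste(".ga ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, data = d, method = method)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y_train - mean(y_train))^2)
  structure(
    list(
      cpg_ids = cpg_ids,
      fit = fit,
      r2_train = r2,
      basis_dim = basis_dim,
      method = method,
      n_train = nrow(X_train),
      train_ids = rownames(X_train),
      train_range = apply(X_train[, cpg_ids, drop = FALSE], 2, range)
    ),
    class = "ga_clock"
  )
}

#' @export
print.ga_clock <- function(x, ...) {
  cat(sprintf("<ga_clock> %d CpGs, trained on n = %d, training R^2 = %.3f\n",
              length(x$cpg_ids), x$n_train, x$r2_train))
  invisible(x)
}

#' Predict gestational age from methylation
#'
#' Evaluates a clock on a beta matrix. GAM clocks sum their per-CpG smooths
#' plus intercept; beyond the training beta range the cubic regression
#' spline extends linearly, and such samples are flagged with a warning and
#' in the `extrapolated` attribute. The lasso baseline predicts linearly.
#'
#' @param model A `ga_clock` or `ga_lasso_clock`.
#' @param X Beta matrix containing (at least) the clock's CpGs as columns.
#' @return Numeric vector of predicted GA in days, named by sample id when
#'   `X` has rownames; GAM predictions carry a logical `extrapolated`
#'   attribute per sample.
#' @export
predict_ga <- function(model, X) UseMethod("predict_ga")

check_clock_cpgs <- function(cpg_ids, X) {
  missing <- setdiff(cpg_ids, colnames(X))
  if (length(missing)) {
    abort(sprintf("matrix is missing clock CpG(s): %s",
                  paste(missing, collapse = ", ")))
  }
}

#' @rdname predict_ga
#' @export
predict_ga.ga_clock <- function(model, X) {
  assert_beta_matrix(X)
  check_clock_cpgs(model$cpg_ids, X)
  newd <- as.data.frame(X[, model$cpg_ids, drop = FALSE])
  pred <- as.numeric(mgcv::predict.gam(model$fit, newdata = newd))
  lo <- model$train_range[1, model$cpg_ids]
  hi <- model$train_range[2, model$cpg_ids]
  out_of_range <- rowSums(
    sweep(newd, 2, lo, "<") | sweep(newd, 2, hi, ">")
  ) > 0
  if (any(out_of_range)) {
    warn(sprintf(
      "%d sample(s) outside the training beta range; spline extended linearly",
      sum(out_of_range)
    ))
  }
  names(pred) <- rownames(X)
  attr(pred, "extrapolated") <- unname(out_of_range)
  pred
}

#' Train the lasso baseline clock
#'
#' The conventional penalized-regression clock: a cross-validation-tuned
#' lasso fit directly on the training set, predicting GA as a linear
#' combination of its nonzero CpGs. Serves as the comparison point for the
#' nested GAM clocks.
#'
#' @inheritParams choose_lambda_cv
#' @return A list of class `ga_lasso_clock`: the glmnet fit at the chosen
#'   penalty, `lambda`, `cpg_ids` (nonzero CpGs), `n_train`, `train_ids`.
#' @export
train_lasso_clock <- function(X, y, folds = 10, seed = 1L) {
  lam <- choose_lambda_cv(X, y, folds = folds, seed = seed)
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lam, standardize = TRUE,
                        thresh = 1e-12, maxit = 1e6)
  b <- as.numeric(fit$beta)
  structure(
    list(
      fit = fit,
      lambda = lam,
      cpg_ids = colnames(X)[abs(b) > 1e-12],
      n_train = nrow(X),
      train_ids = rownames(X)
    ),
    class = "ga_lasso_clock"
  )
}

#' @export
print.ga_lasso_clock <- function(x, ...) {
  cat(sprintf("<ga_lasso_clock> %d nonzero CpGs at lambda = %.4g, n = %d\n",
              length(x$cpg_ids), x$lambda, x$n_train))
  invisible(x)
}

#' @rdname predict_ga
#' @export
predict_ga.ga_lasso_clock <- function(model, X) {
  assert_beta_matrix(X)
  feats <- rownames(model$fit$beta)
  check_clock_cpgs(feats, X)
  pred <- as.numeric(
    glmnet::predict.glmnet(model$fit, newx = X[, feats, drop = FALSE],
                           s = model$lambda)
  )
  names(pred) <- rownames(X)
  pred
}

#' @export
tidy.ga_clock <- function(x, ...) {
  s <- mgcv::summary.gam(x$fit)
  tibble::tibble(
    cpg_id = x$cpg_ids,
    edf = unname(s$edf),
    ref_df = unname(s$s.table[, "Ref.df"]),
    f_statistic = unname(s$s.table[, "F"]),
    p_value = unname(s$s.table[, "p-value"])
  )
}

#' @export
glance.ga_clock <- function(x, ...) {
  tibble::tibble(
    k = length(x$cpg_ids),
    n_train = x$n_train,
    r2_train = x$r2_train,
    total_edf = sum(x$fit$edf),
    gcv = x$fit$gcv.ubre
  )
}

#' @export
glance.ga_lasso_clock <- function(x, ...) {
  tibble::tibble(
    n_cpgs = length(x$cpg_ids),
    lambda = x$lambda,
    n_train = x$n_train
  )
}
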