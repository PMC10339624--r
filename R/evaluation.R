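#' Median absolute deviation between predicted and observed GA
#'
#' The paired prediction-error median: `median(|pred - obs|)` in days (for
#' even counts, the mean of the two central order statistics). This is the
#' accuracy metric of cord-blood GA clocks, not the robust scale estimator
#' of the same name.
#'
#' @param pred Predicted GA in days.
#' @param obs Observed (ultrasound-estimated) GA in days.
#' @return A single number, days.
#' @export
#' @examples
#' mad_days(c(1, 2, 3, 10) + 100, rep(100, 4)) # 2.5
mad_days <- function(pred, obs) {
  if (length(pred) != length(obs)) abort("pred and obs must have equal length")
  if (length(pred) < 1) abort("need at least one pair")
  stats::median(abs(pred - obs))
}

#' R-squared between predicted and observed GA
#'
#' The headline precision metric. `method = "corr"` (default) is the
#' squared Pearson correlation between predictions and observations —
#' invariant to affine miscalibration of the predictor. `method =
#' "variance_explained"` is `1 - SS_res/SS_tot`, which penalises
#' miscalibration and can go negative; negative values are floored at 0
#' and flagged via the `floored` attribute. A constant predictor has no
#' defined correlation and is reported as 0 with the `degenerate`
#' attribute set.
#'
#' @inheritParams mad_days
#' @param method `"corr"` or `"variance_explained"`.
#' @return A single number in `[0, 1]`.
#' @export
r_squared <- function(pred, obs, method = c("corr", "variance_explained")) {
  method <- match.arg(method)
  if (length(pred) != length(obs)) abort("pred and obs must have equal length")
  if (length(pred) < 3) abort("need at least 3 pairs")
  if (stats::sd(obs) == 0) abort("obs is constant; R-squared undefined")
  if (method == "corr") {
    if (stats::sd(pred) == 0) {
      warn("constant predictor: correlation undefined, reporting 0")
      return(structure(0, degenerate = TRUE))
    }
    stats::cor(pred, obs)^2
  } else {
    r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    if (r2 < 0) {
      warn("variance explained below 0; floored")
      return(structure(0, floored = TRUE))
    }
    r2
  }
}

#' MM-type robust calibration regression
#'
#' Regresses observed on predicted GA with an MM-estimator: a
#' high-breakdown S-estimate initialisation followed by redescending
#' M-iteration under Tukey's bisquare loss tuned to 95% Gaussian
#' efficiency. A well-calibrated clock gives slope near 1 and intercept
#' near 0 even in the presence of gross outliers, where ordinary least
#' squares would be dragged off.
#'
#' @param x Predicted GA in days.
#' @param y Observed GA in days.
#' @param max_iter Maximum M-iterations (default 200).
#' @return A list of class `robust_fit`: `slope`, `intercept`, `converged`.
#' @export
robust_fit <- function(x, y, max_iter = 200) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 5) abort("need at least 5 points for an MM fit")

  # canonical sample order + a frozen local RNG stream make the randomized
  # S-estimate subsampling deterministic and invariant to input order; the
  # caller's RNG state is untouched
  o <- order(x, y)
  xs <- x[o]
  ys <- y[o]
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(104729L)

  fit <- tryCatch(
    suppressWarnings(
      MASS::rlm(ys ~ xs, method = "MM", psi = MASS::psi.bisquare, c = 4.685,
                maxit = max_iter, acc = 1e-8)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    return(structure(
      list(slope = unname(stats::coef(fit)[2]),
           intercept = unname(stats::coef(fit)[1]),
           converged = isTRUE(fit$converged)),
      class = "robust_fit"
    ))
  }
  # a (near-)exact fit on at least half the points drives the robust scale
  # to 0, where the S/M iterations are undefined; the high-breakdown
  # least-trimmed-squares fit is the limiting MM solution there
  lts <- MASS::lqs(ys ~ xs, method = "lts")
  structure(
    list(slope = unname(stats::coef(lts)[2]),
         intercept = unname(stats::coef(lts)[1]),
         converged = TRUE),
    class = "robust_fit"
  )
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("<robust_fit> obs = %.3f * pred %+0.3f d%s\n",
              x$slope, x$intercept,
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' Score a series of clocks on a held-out test set
#'
#' Evaluates each nested GAM clock and the lasso baseline on the same test
#' samples, reporting precision (R-squared, both conventions), accuracy
#' (median absolute deviation in days), the MM-type calibration slope and
#' intercept, and preterm-subset metrics (GA < 259 days: MAD and mean
#' signed error). Refuses to run if any test sample id appears in a
#' clock's training set (leakage guard).
#'
#' @param models List of `ga_clock` objects (typically from
#'   [build_nested_clocks()]).
#' @param baseline A `ga_lasso_clock`, or `NULL` to skip the baseline row.
#' @param X_test Test beta matrix, samples x CpGs, rownames = sample ids.
#' @param y_test Observed GA in days for the test samples.
#' @return A tibble of class `performance_curve`, one row per clock plus
#'   one `model = "lasso"` baseline row, with columns `model`, `k`,
#'   `n_cpgs`, `n_test`, `r2_corr`, `r2_var`, `mad_days`, `robust_slope`,
#'   `robust_intercept`, `robust_converged`, `preterm_n`, `preterm_mad`,
#'   `preterm_bias`. The per-sample predictions are kept in the
#'   `predictions` attribute for audit.
#' @export
evaluate_clock_series <- function(models, baseline, X_test, y_test) {
  assert_beta_matrix(X_test)
  assert_response(y_test, nrow(X_test))
  test_ids <- rownames(X_test)
  if (is.null(test_ids)) abort("X_test must have sample ids as rownames")

  all_models <- c(models, if (!is.null(baseline)) list(baseline))
  for (m in all_models) {
    leaked <- intersect(m$train_ids, test_ids)
    if (length(leaked)) {
      abort(sprintf("train/test leakage: %d shared sample id(s), e.g. %s",
                    length(leaked), leaked[1]))
    }
  }

  preterm <- y_test < 259
  score_one <- function(pred, label, k, n_cpgs) {
    rf <- robust_fit(pred, y_test)
    tibble::tibble(
      model = label, k = k, n_cpgs = n_cpgs, n_test = length(y_test),
      r2_corr = as.numeric(r_squared(pred, y_test, "corr")),
      r2_var = as.numeric(r_squared(pred, y_test, "variance_explained")),
      mad_days = mad_days(pred, y_test),
      robust_slope = rf$slope, robust_intercept = rf$intercept,
      robust_converged = rf$converged,
      preterm_n = sum(preterm),
      preterm_mad = if (any(preterm)) mad_days(pred[preterm], y_test[preterm]) else NA_real_,
      preterm_bias = if (any(preterm)) mean(pred[preterm] - y_test[preterm]) else NA_real_
    )
  }

  rows <- list()
  pred_rows <- list()
  for (m in models) {
    k <- length(m$cpg_ids)
    pred <- suppressWarnings(predict_ga(m, X_test))
    rows[[length(rows) + 1L]] <- score_one(pred, "gam", k, k)
    pred_rows[[length(pred_rows) + 1L]] <- tibble::tibble(
      sample_id = test_ids, ga_obs = y_test, ga_pred = as.numeric(pred),
      model = "gam", model_k = k
    )
  }
  if (!is.null(baseline)) {
    pred <- predict_ga(baseline, X_test)
    rows[[length(rows) + 1L]] <-
      score_one(pred, "lasso", NA_integer_, length(baseline$cpg_ids))
    pred_rows[[length(pred_rows) + 1L]] <- tibble::tibble(
      sample_id = test_ids, ga_obs = y_test, ga_pred = as.numeric(pred),
      model = "lasso", model_k = NA_integer_
    )
  }

  curve <- dplyr::bind_rows(rows)
  structure(
    curve,
    predictions = dplyr::bind_rows(pred_rows),
    class = c("performance_curve", class(curve))
  )
}

#' @export
tidy.performance_curve <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.performance_curve <- function(x, ...) {
  gam_rows <- dplyr::filter(x, .data$model == "gam")
  tibble::tibble(
    n_models = nrow(x),
    k_max = max(gam_rows$k),
    best_r2 = max(x$r2_corr),
    best_mad_days = min(x$mad_days)
  )
}
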