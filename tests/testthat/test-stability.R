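test_that("cross-validated penalty tuning is deterministic and signal-sensitive", {
  co <- planted_cohort(n = 200, p = 300, seed = 3)
  X <- co$betas
  y <- co$samples$ga_days
  lam1 <- choose_lambda_cv(X, y, folds = 5, seed = 11)
  lam2 <- choose_lambda_cv(X, y, folds = 5, seed = 11)
  expect_identical(lam1, lam2)

  # strong planted signal -> nonempty model at the chosen penalty
  expect_gt(length(fit_lasso(X, y, lam1)), 0)

  # pure noise with p >> n -> penalty near the path maximum, few selections
  set.seed(42)
  Xn <- toy_matrix(60, 400, seed = 42)
  y_noise <- rnorm(60)
  lam_null <- choose_lambda_cv(Xn, y_noise, folds = 5, seed = 11)
  path_max <- max(glmnet::glmnet(Xn, y_noise, alpha = 1)$lambda)
  expect_gt(lam_null, 0.25 * path_max)
  expect_lt(length(fit_lasso(Xn, y_noise, lam_null)), 20)

  expect_error(choose_lambda_cv(X, rep(1, nrow(X))), "constant")
})

test_that("fit_lasso matches closed-form oracles", {
  # lambda >= lambda_max -> empty selection
  X <- toy_matrix(50, 5, seed = 2)
  set.seed(2)
  y <- rnorm(50) + 3 * X[, 1]
  expect_length(fit_lasso(X, y, lam = 1e3), 0)

  # lambda = 0, n > p, well-conditioned -> the least-squares active set
  sel0 <- fit_lasso(X, y, lam = 0)
  ls <- coef(lm(y ~ X))[-1]
  expect_setequal(sel0, colnames(X)[abs(ls) > 1e-12])

  # one-dimensional soft threshold: selected iff lam < |cov_n(x, y)| for
  # a unit-variance standardized feature
  x1 <- X[, 1, drop = FALSE]
  n <- nrow(x1)
  xs <- (x1 - mean(x1)) / (sd(x1) * sqrt((n - 1) / n))
  thr <- abs(mean(xs * (y - mean(y))))
  expect_identical(fit_lasso(x1, y, lam = thr * 0.5), colnames(x1))
  expect_length(fit_lasso(x1, y, lam = thr * 1.5), 0)

  # zero-variance feature is never selected and never errors
  Xz <- cbind(X, zzz = 0.5)
  expect_false("zzz" %in% fit_lasso(Xz, y, lam = 0.001))
})

test_that("per-run selected-set size is monotone non-increasing in lambda", {
  X <- toy_matrix(60, 30, seed = 5)
  set.seed(5)
  y <- rnorm(60) + X[, 1] - 2 * X[, 2]
  lams <- c(0.001, 0.005, 0.02, 0.08, 0.3)
  sizes <- sapply(lams, function(l) length(fit_lasso(X, y, l)))
  expect_true(all(diff(sizes) <= 0))
})

test_that("selection profiles obey their counting and determinism contracts", {
  co <- planted_cohort(n = 120, p = 150, seed = 6)
  X <- co$betas
  y <- co$samples$ga_days
  lam <- choose_lambda_cv(X, y, seed = 1)
  cfg <- selection_config(n_subsamples = 25, seed = 2)

  prof <- run_stability_selection(X, y, lam, cfg)
  expect_equal(prof$selection_probability,
               prof$selection_count / attr(prof, "B"))

  # oracle: recount probabilities from the persisted per-run log
  runs <- attr(prof, "runs")
  recount <- table(factor(unlist(runs$selected), levels = prof$cpg_id))
  expect_identical(as.integer(recount), prof$selection_count)

  # determinism
  prof2 <- run_stability_selection(X, y, lam, cfg)
  expect_identical(serialize(prof, NULL), serialize(prof2, NULL))

  # master-seed substreams: growing B preserves the earlier runs
  prof_big <- run_stability_selection(X, y, lam,
                                      selection_config(n_subsamples = 40,
                                                       seed = 2))
  expect_identical(attr(prof_big, "runs")$selected[1:25], runs$selected)

  # B = 1 -> probabilities are all 0 or 1
  p1 <- run_stability_selection(X, y, lam,
                                selection_config(n_subsamples = 1, seed = 3))
  expect_true(all(p1$selection_probability %in% c(0, 1)))
})

test_that("feature order does not leak into the profile", {
  # subsample size (n/2 = 100) exceeds p so each half-sample lasso has a
  # unique solution and column order is immaterial
  co <- planted_cohort(n = 200, p = 50, seed = 12)
  X <- co$betas
  y <- co$samples$ga_days
  cfg <- selection_config(n_subsamples = 10, seed = 4)
  prof <- run_stability_selection(X, y, 0.05, cfg)
  set.seed(13)
  perm <- sample(ncol(X))
  prof_p <- run_stability_selection(X[, perm], y, 0.05, cfg)
  merged <- merge(as.data.frame(prof), as.data.frame(prof_p), by = "cpg_id")
  expect_equal(merged$selection_count.x, merged$selection_count.y)
})

test_that("zero-variance CpGs get probability zero", {
  X <- toy_matrix(80, 10, seed = 7)
  X[, 3] <- 0.4
  set.seed(7)
  y <- rnorm(80) + X[, 1]
  prof <- run_stability_selection(X, y, 0.01,
                                  selection_config(n_subsamples = 20, seed = 1))
  expect_equal(prof$selection_probability[3], 0)
})

test_that("permutation q equals the mean of its run log and is deterministic", {
  X <- toy_matrix(40, 20, seed = 8)
  set.seed(8)
  y <- rnorm(40) + 2 * X[, 1]
  cfg <- selection_config(n_subsamples = 50, seed = 9)
  q <- estimate_q_permutation(X, y, 0.01, cfg)
  expect_equal(as.numeric(q), mean(attr(q, "runs")$n_selected))

  q2 <- estimate_q_permutation(X, y, 0.01, cfg)
  expect_equal(as.numeric(q), as.numeric(q2))

  # penalty beyond every permuted path maximum -> q = 0
  q0 <- estimate_q_permutation(X, y, 1e3, cfg)
  expect_equal(as.numeric(q0), 0)
})

test_that("the false-discovery bound inverts and round-trips", {
  expect_equal(compute_threshold(1, 593.8, 769139)$pi_thr, 0.729,
               tolerance = 0.0005)
  expect_equal(compute_threshold(0.5, 450.5, 769139)$pi_thr, 0.764,
               tolerance = 0.0005)
  expect_equal(compute_threshold(2, 593.8, 769139)$pi_thr, 0.6146,
               tolerance = 0.0001)

  # q^2 = E_V * p forces the cap exactly
  expect_equal(compute_threshold(1, 10, 100)$pi_thr, 1.0)
  expect_warning(compute_threshold(1, 20, 100), "capped")

  # round-trip: plugging the threshold back recovers the bound value
  b <- compute_threshold(0.7, 123.4, 5e5)
  expect_equal(b$q^2 / ((2 * b$pi_thr - 1) * b$p), b$E_V,
               tolerance = 1e-9 * b$E_V)

  expect_error(compute_threshold(0, 1, 10), "E_V")
})

test_that("stable_features applies an inclusive, tie-broken cutoff", {
  prof <- tibble::tibble(
    cpg_id = c("a", "b", "c"),
    selection_count = c(100, 73, 72),
    selection_probability = c(1.0, 0.73, 0.72)
  )
  class(prof) <- c("selection_profile", class(prof))
  out <- stable_features(prof, 0.729)
  expect_identical(out$cpg_id, c("a", "b"))
  expect_identical(nrow(stable_features(prof, 1.0)), 1L)

  # ties broken by id ascending
  prof$selection_probability <- c(0.9, 0.9, 0.2)
  expect_identical(stable_features(prof, 0.8)$cpg_id, c("a", "b"))

  prof$selection_probability <- c(0.1, 0.2, 0.3)
  expect_identical(nrow(stable_features(prof, 0.9)), 0L)
  expect_error(stable_features(prof, 0.4), "pi_thr")
})

test_that("a strongly planted CpG is stably selected", {
  co <- planted_cohort(n = 300, p = 2000, target_r2 = 0.5, seed = 21)
  X <- co$betas
  y <- co$samples$ga_days
  lam <- choose_lambda_cv(X, y, seed = 21)
  prof <- run_stability_selection(X, y, lam,
                                  selection_config(n_subsamples = 100,
                                                   seed = 21))
  causal <- co$truth$cpg_id[1]
  p_causal <- prof$selection_probability[prof$cpg_id == causal]
  expect_gte(p_causal, 0.9)
  expect_true(causal %in% stable_features(prof, 0.9)$cpg_id)
})
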