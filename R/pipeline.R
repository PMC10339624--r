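#' Pipeline configuration
#'
#' Bundles every choice the end-to-end run needs: the cohort source
#' (exactly one of a synthetic [cohort_config()] or paths to a beta matrix
#' + sample sheet), the stability-selection settings, the false-discovery
#' budget and its convention, the clock sizes, and the train/test split.
#'
#' `ev_convention` controls how `fd_budget` enters the false-discovery
#' bound: `"half"` (default) plugs `fd_budget / 2` in as the bound value —
#' the convention under which a budget of two false discoveries yields the
#' 0.729-style thresholds — while `"stated"` plugs the budget in verbatim.
#'
#' @param cohort A [cohort_config()] for a synthetic cohort, or `NULL`.
#' @param beta_path,sheet_path Paths to a beta matrix TSV and sample sheet
#'   CSV, or `NULL`.
#' @param selection A [selection_config()].
#' @param lam Lasso penalty for stability selection: `"cv"` (tune on the
#'   training set) or a fixed number.
#' @param fd_budget Allowed expected false discoveries in the stable set.
#' @param ev_convention `"half"` or `"stated"` (see above).
#' @param k_max Largest nested clock size.
#' @param train_fraction,split_seed Train/test split settings.
#' @param out_dir Output directory for the artifact bundle.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL,
                            beta_path = NULL, sheet_path = NULL,
                            selection = selection_config(n_subsamples = 100),
                            lam = "cv",
                            fd_budget = 2,
                            ev_convention = c("half", "stated"),
                            k_max = 15,
                            train_fraction = 0.8,
                            split_seed = 1L,
                            out_dir = tempfile("stabclock_run_")) {
  ev_convention <- match.arg(ev_convention)
  synthetic <- !is.null(cohort)
  from_files <- !is.null(beta_path) || !is.null(sheet_path)
  if (synthetic == from_files) {
    abort("exactly one cohort source required: `cohort` or `beta_path`+`sheet_path`")
  }
  if (from_files && (is.null(beta_path) || is.null(sheet_path))) {
    abort("both beta_path and sheet_path are required for a file cohort")
  }
  if (!identical(lam, "cv") && (!is.numeric(lam) || lam < 0)) {
    abort("lam must be \"cv\" or a non-negative number")
  }
  if (fd_budget <= 0) abort("fd_budget must be > 0")
  structure(
    list(cohort = cohort, beta_path = beta_path, sheet_path = sheet_path,
         selection = selection, lam = lam, fd_budget = fd_budget,
         ev_convention = ev_convention, k_max = as.integer(k_max),
         train_fraction = train_fraction, split_seed = as.integer(split_seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

pipeline_stage <- function(name, expr, out_dir) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("FAILED at stage: %s\n%s", name, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full selection-to-clock pipeline
#'
#' Executes, in order: cohort acquisition; train/test split; penalty tuning
#' by cross-validation on the training set; stability selection on the
#' training set; permutation calibration of `q` and threshold computation;
#' extraction of the stable set; univariate GAM ranking of the stable
#' CpGs; nested GAM clocks for k = 1..k_max; the lasso baseline clock; and
#' test-set evaluation. Every output plus a manifest (configuration,
#' seeds, versions, stages) is written to `config$out_dir`; any stage
#' error aborts with the stage name and leaves a `FAILED` marker next to
#' the partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory artifacts: `cohort`,
#'   `split`, `lam`, `profile`, `bound`, `stable`, `ranking`, `clocks`,
#'   `baseline`, `curve`, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))
  stages <- character()
  note <- function(s) stages <<- c(stages, s)

  cohort <- pipeline_stage("cohort", {
    if (!is.null(config$cohort)) {
      co <- generate_cohort(config$cohort)
      write_cohort(co, file.path(out, "cohort"))
      co
    } else {
      X <- read_beta_matrix(config$beta_path)
      sheet <- read_sample_sheet(config$sheet_path, matrix_ids = rownames(X))
      structure(list(betas = X, samples = sheet,
                     truth = tibble::tibble(cpg_id = character(),
                                            link_type = character(),
                                            params = list()),
                     config = NULL),
                class = "dnam_cohort")
    }
  }, out)
  note("cohort")

  split <- pipeline_stage("split", {
    sp <- split_train_test(cohort, config$train_fraction, config$split_seed)
    readr::write_csv(
      dplyr::bind_rows(
        dplyr::mutate(sp$train$samples, set = "train"),
        dplyr::mutate(sp$test$samples, set = "test")
      ),
      file.path(out, "split.csv"), progress = FALSE
    )
    sp
  }, out)
  note("split")

  X_tr <- split$train$betas
  y_tr <- split$train$samples$ga_days

  lam <- pipeline_stage("lambda", {
    l <- if (identical(config$lam, "cv")) {
      choose_lambda_cv(X_tr, y_tr, folds = config$selection$cv_folds,
                       seed = config$selection$seed)
    } else config$lam
    jsonlite::write_json(list(lambda = l, rule = "lambda.min"),
                         file.path(out, "lambda.json"), auto_unbox = TRUE,
                         digits = NA)
    l
  }, out)
  note("lambda")

  profile <- pipeline_stage("stability_selection", {
    pr <- run_stability_selection(X_tr, y_tr, lam, config$selection)
    write_selection_profile(pr, out)
    pr
  }, out)
  note("stability_selection")

  bound <- pipeline_stage("threshold", {
    q <- estimate_q_permutation(X_tr, y_tr, lam, config$selection)
    ev <- if (config$ev_convention == "half") config$fd_budget / 2 else config$fd_budget
    b <- compute_threshold(ev, as.numeric(q), ncol(X_tr))
    jsonlite::write_json(
      list(E_V = b$E_V, q = b$q, p = b$p, pi_thr = b$pi_thr,
           fd_budget = config$fd_budget, convention = config$ev_convention),
      file.path(out, "threshold.json"), auto_unbox = TRUE, digits = NA
    )
    b
  }, out)
  note("threshold")

  stable <- pipeline_stage("stable_set", {
    s <- stable_features(profile, bound)
    if (nrow(s) == 0) abort("no CpG passed the stability threshold")
    readr::write_tsv(s, file.path(out, "stable_set.tsv"), progress = FALSE)
    s
  }, out)
  note("stable_set")

  ranking <- pipeline_stage("gam_ranking", {
    r <- screen_cpgs(X_tr, y_tr, cpg_ids = stable$cpg_id)
    readr::write_tsv(r, file.path(out, "gam_ranking.tsv"), progress = FALSE)
    r
  }, out)
  note("gam_ranking")

  k_max <- min(config$k_max, nrow(stable))
  clocks <- pipeline_stage("nested_clocks", {
    build_nested_clocks(X_tr, y_tr, rank_by_r2(ranking), k_max)
  }, out)
  note("nested_clocks")

  baseline <- pipeline_stage("lasso_baseline", {
    train_lasso_clock(X_tr, y_tr, folds = config$selection$cv_folds,
                      seed = config$selection$seed)
  }, out)
  note("lasso_baseline")

  curve <- pipeline_stage("evaluation", {
    cv <- evaluate_clock_series(clocks, baseline, split$test$betas,
                                split$test$samples$ga_days)
    readr::write_tsv(tibble::as_tibble(cv),
                     file.path(out, "performance_curve.tsv"), progress = FALSE)
    readr::write_tsv(attr(cv, "predictions"),
                     file.path(out, "predictions.tsv"), progress = FALSE)
    cv
  }, out)
  note("evaluation")

  manifest <- list(
    package = "stabclock",
    version = as.character(utils::packageVersion("stabclock")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages = stages,
    lambda = lam,
    k_max = k_max,
    seeds = list(selection = config$selection$seed,
                 split = config$split_seed,
                 cohort = if (!is.null(config$cohort)) config$cohort$seed),
    config = unclass(config)[setdiff(names(config), "out_dir")]
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  invisible(list(cohort = cohort, split = split, lam = lam,
                 profile = profile, bound = bound, stable = stable,
                 ranking = ranking, clocks = clocks, baseline = baseline,
                 curve = curve, out_dir = out))
}
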