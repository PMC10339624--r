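# Readers and writers for the package's on-disk formats. Matrices are
# stored CpGs-as-rows (the methylation-array convention) and transposed to
# samples-as-rows in memory for regression.

#' Read a beta-value matrix
#'
#' Expects a TSV (or CSV) with CpG ids in the first column and one column
#' per sample; values are validated to lie in `[0, 1]` with no missing
#' entries, and duplicate CpG or sample ids are rejected. The returned
#' matrix is transposed to the in-memory samples x CpGs orientation.
#'
#' @param path File path; `.csv` is read comma-separated, anything else
#'   tab-separated (gzipped files are handled transparently).
#' @return Numeric matrix, samples x CpGs.
#' @export
read_beta_matrix <- function(path) {
  reader <- if (grepl("\\.csv(\\.gz)?$", path)) readr::read_csv else readr::read_tsv
  d <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(d) < 2) abort("beta matrix needs an id column plus >= 1 sample")
  cpg_ids <- as.character(d[[1]])
  if (anyDuplicated(cpg_ids)) {
    abort(sprintf("duplicate CpG id(s): %s",
                  paste(unique(cpg_ids[duplicated(cpg_ids)]), collapse = ", ")))
  }
  sample_ids <- colnames(d)[-1]
  if (anyDuplicated(sample_ids)) abort("duplicate sample id(s) in header")
  M <- as.matrix(d[, -1])
  if (!is.numeric(M)) abort("non-numeric beta values")
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    abort(sprintf("missing beta at CpG %s, sample %s",
                  cpg_ids[bad[1]], sample_ids[bad[2]]))
  }
  out <- M < 0 | M > 1
  if (any(out)) {
    bad <- which(out, arr.ind = TRUE)[1, ]
    abort(sprintf("beta value %g outside [0,1] at CpG %s, sample %s",
                  M[bad[1], bad[2]], cpg_ids[bad[1]], sample_ids[bad[2]]))
  }
  X <- t(M)
  dimnames(X) <- list(sample_ids, cpg_ids)
  X
}

#' Write a beta-value matrix
#'
#' CpGs as rows, samples as columns, tab-separated, 6 decimal places.
#'
#' @param X Numeric matrix, samples x CpGs (in-memory orientation).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(X, path) {
  assert_beta_matrix(X)
  M <- t(X)
  d <- tibble::as_tibble(as.data.frame(formatC(M, format = "f", digits = 6)),
                         .name_repair = "minimal")
  colnames(d) <- rownames(X)
  d <- dplyr::bind_cols(tibble::tibble(cpg_id = colnames(X)), d)
  readr::write_tsv(d, path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with columns `sample_id`, `ga_days`, `sex`. GA must be finite and
#' positive; sex values are normalised to `male`/`female`/`unknown`.
#'
#' @param path CSV path.
#' @param matrix_ids Optional sample ids (e.g. `rownames` of a beta matrix)
#'   the sheet must match one-to-one; mismatches are reported by id.
#' @return Tibble: `sample_id`, `ga_days`, `sex`.
#' @export
read_sample_sheet <- function(path, matrix_ids = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "ga_days", "sex")
  miss <- setdiff(need, colnames(d))
  if (length(miss)) {
    abort(sprintf("sample sheet missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  d <- d |> dplyr::mutate(
    sample_id = as.character(.data$sample_id),
    ga_days = as.numeric(.data$ga_days),
    sex = dplyr::case_when(
      tolower(.data$sex) %in% c("m", "male") ~ "male",
      tolower(.data$sex) %in% c("f", "female") ~ "female",
      TRUE ~ "unknown"
    )
  )
  if (anyDuplicated(d$sample_id)) abort("duplicate sample ids in sheet")
  if (any(!is.finite(d$ga_days)) || any(d$ga_days <= 0)) {
    bad <- d$sample_id[!is.finite(d$ga_days) | d$ga_days <= 0]
    abort(sprintf("non-positive or missing ga_days for: %s",
                  paste(bad, collapse = ", ")))
  }
  if (!is.null(matrix_ids)) {
    extra <- setdiff(d$sample_id, matrix_ids)
    missing <- setdiff(matrix_ids, d$sample_id)
    if (length(extra) || length(missing)) {
      abort(sprintf(
        "sample sheet / matrix mismatch; in sheet only: [%s]; in matrix only: [%s]",
        paste(extra, collapse = ", "), paste(missing, collapse = ", ")
      ))
    }
    d <- d[match(matrix_ids, d$sample_id), ]
  }
  tibble::as_tibble(d[, need])
}

#' Write a cohort to disk
#'
#' Beta matrix TSV (CpGs as rows, 6 decimals), sample sheet CSV, and a
#' truth table TSV (`cpg_id`, `link_type`, `params` as a JSON string).
#'
#' @param cohort A `dnam_cohort`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dnam_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    betas = file.path(dir, "betas.tsv"),
    samples = file.path(dir, "samples.csv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_beta_matrix(cohort$betas, paths["betas"])
  readr::write_csv(cohort$samples, paths["samples"], progress = FALSE)
  truth <- cohort$truth |>
    dplyr::mutate(params = purrr::map_chr(
      .data$params, ~ jsonlite::toJSON(.x, auto_unbox = TRUE)
    ))
  readr::write_tsv(truth, paths["truth"], progress = FALSE)
  invisible(paths)
}

#' Write a selection profile and its run log
#'
#' @param profile A `selection_profile`.
#' @param dir Output directory.
#' @return Named character vector of files written, invisibly.
#' @export
write_selection_profile <- function(profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(profile = file.path(dir, "selection_profile.tsv"),
             runs = file.path(dir, "selection_runs.tsv"))
  readr::write_tsv(tibble::as_tibble(profile), paths["profile"],
                   progress = FALSE)
  runs <- attr(profile, "runs") |>
    dplyr::mutate(selected = purrr::map_chr(
      .data$selected, paste, collapse = ","
    ))
  readr::write_tsv(runs, paths["runs"], progress = FALSE)
  invisible(paths)
}
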