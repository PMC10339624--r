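#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a selection profile
#'
#' Selection probability per CpG in matrix order, with the stability
#' threshold (if given) and the 0.5 coin-flip line.
#'
#' @param object A `selection_profile`.
#' @param pi_thr Optional threshold (number or `fd_bound`) drawn as a
#'   dashed line; features above it are highlighted.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.selection_profile <- function(object, pi_thr = NULL, ...) {
  if (inherits(pi_thr, "fd_bound")) pi_thr <- pi_thr$pi_thr
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(
      index = dplyr::row_number(),
      stable = if (!is.null(pi_thr)) .data$selection_probability >= pi_thr else FALSE
    )
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$index, .data$selection_probability)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$stable), size = 0.6,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#E69F00")) +
    ggplot2::geom_hline(yintercept = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "CpG (matrix order)", y = "Selection probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(pi_thr)) {
    p <- p + ggplot2::geom_hline(yintercept = pi_thr, linetype = "dashed")
  }
  p
}

#' Plot a performance curve
#'
#' Test-set precision (R-squared) and accuracy (MAD, days) against the
#' number of CpGs in the clock; the lasso baseline is the red point at its
#' own CpG count.
#'
#' @param object A `performance_curve` from [evaluate_clock_series()].
#' @param ... Unused.
#' @return A ggplot (faceted by metric).
#' @export
autoplot.performance_curve <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(x = dplyr::coalesce(as.numeric(.data$k),
                                      as.numeric(.data$n_cpgs))) |>
    tidyr::pivot_longer(c("r2_corr", "mad_days"), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
                                         r2_corr = "R²",
                                         mad_days = "MAD (days)"))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$value)) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$model == "gam")) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$model), size = 2) +
    ggplot2::scale_colour_manual(values = c(gam = "black", lasso = "red")) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "CpGs in clock", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the DNAm--GA relationship for a clock's CpGs
#'
#' Scatter of beta value against GA for each clock CpG with the fitted
#' smooth overlaid (evaluated with the other CpGs held at their training
#' medians), the per-CpG analogue of the usual clock diagnostic panels.
#'
#' @param clock A `ga_clock`.
#' @param X Beta matrix containing the clock CpGs (typically the training
#'   matrix).
#' @param y GA in days for the rows of `X`.
#' @return A ggplot faceted by CpG.
#' @export
plot_clock_smooths <- function(clock, X, y) {
  stopifnot(inherits(clock, "ga_clock"))
  check_clock_cpgs(clock$cpg_ids, X)
  pts <- purrr::map_dfr(clock$cpg_ids, function(id) {
    tibble::tibble(cpg_id = id, beta = X[, id], ga_days = y)
  })
  med <- apply(X[, clock$cpg_ids, drop = FALSE], 2, stats::median)
  curves <- purrr::map_dfr(clock$cpg_ids, function(id) {
    grid <- seq(min(X[, id]), max(X[, id]), length.out = 100)
    newd <- as.data.frame(t(replicate(100, med)))
    colnames(newd) <- clock$cpg_ids
    newd[[id]] <- grid
    tibble::tibble(cpg_id = id, beta = grid,
                   ga_days = as.numeric(mgcv::predict.gam(clock$fit, newd)))
  })
  ggplot2::ggplot(pts, ggplot2::aes(.data$ga_days, .data$beta)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.4) +
    ggplot2::geom_line(data = curves, colour = "#E69F00", linewidth = 1,
                       orientation = "y") +
    ggplot2::facet_wrap(~cpg_id, scales = "free_y") +
    ggplot2::labs(x = "Gestational age (days)", y = "Beta value") +
    ggplot2::theme_minimal()
}
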