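# ggplot2 autoplot methods for the main result types.

#' Plot the training / validation loss trace
#' @param object a `fold_model`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.fold_model <- function(object, ...) {
  tr <- tidy.fold_model(object)
  tr <- tr[grepl("loss", tr$metric), ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~phase, scales = "free_x") +
    ggplot2::labs(x = "step", y = "cross-entropy (nats/token)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the sorted per-query sensitivity curves
#'
#' Queries sorted by decreasing sensitivity per level; the area under each
#' curve equals the level's mean sensitivity.
#' @param object a `benchmark_result`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.benchmark_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$query_fraction,
                               y = .data$sensitivity,
                               colour = .data$level_name)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "fraction of queries",
                  y = "sensitivity up to first FP", colour = "level") +
    ggplot2::theme_minimal()
}

#' Plot per-level EAT accuracy
#' @param object an `eat_result`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.eat_result <- function(object, ...) {
  acc <- object$accuracy
  acc$level_name <- factor(acc$level_name, levels = acc$level_name)
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$level_name,
                                    y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "hierarchy level (coarse to fine)", y = "accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a structure-head precision/coverage threshold sweep
#'
#' @param predictions list of `per_residue_prediction`.
#' @param truth character vector of true 3Di strings aligned to
#'   `predictions`.
#' @param thresholds confidence grid.
#' @return a ggplot of coverage and precision against the threshold.
#' @export
plot_threshold_sweep <- function(predictions, truth,
                                 thresholds = seq(0, 0.95, by = 0.05)) {
  sweep_tbl <- threshold_sweep(predictions, truth, thresholds)
  long <- tidyr::pivot_longer(sweep_tbl, c("coverage", "precision"),
                              names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "confidence threshold", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Coverage and precision of thresholded head predictions
#'
#' @param predictions list of `per_residue_prediction`.
#' @param truth true 3Di strings.
#' @param thresholds confidence grid.
#' @return tibble with `threshold`, `coverage`, `precision` (precision over
#'   unmasked residues; `NA` when nothing is unmasked).
#' @export
threshold_sweep <- function(predictions, truth,
                            thresholds = seq(0, 0.95, by = 0.05)) {
  conf <- unlist(lapply(predictions, `[[`, "confidence"))
  pred <- unlist(lapply(predictions, function(p) split_chars(p$labels)))
  tru <- unlist(lapply(truth, split_chars))
  stopifnot(length(pred) == length(tru))
  purrr::map_dfr(thresholds, function(th) {
    keep <- conf >= th
    tibble::tibble(threshold = th, coverage = mean(keep),
                   precision = if (any(keep)) mean(pred[keep] == tru[keep])
                   else NA_real_)
  })
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
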