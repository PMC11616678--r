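# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training trace of a translation model
#' @param x a `fold_model`.
#' @param ... unused.
#' @return tibble with `phase`, `step`, `metric`, `value`.
#' @exportS3Method generics::tidy
#' @export
tidy.fold_model <- function(x, ...) {
  if (is.null(x$trace)) return(tibble::tibble(phase = character(),
                                              step = integer(),
                                              metric = character(),
                                              value = numeric()))
  x$trace
}

#' One-row model summary
#' @param x a `fold_model`.
#' @param ... unused.
#' @exportS3Method generics::glance
#' @export
glance.fold_model <- function(x, ...) {
  final <- function(metric) {
    tr <- x$trace
    if (is.null(tr)) return(NA_real_)
    v <- tr$value[tr$metric == metric]
    if (length(v) == 0) NA_real_ else v[length(v)]
  }
  tibble::tibble(
    n_layers = x$dims$n_layers, width = x$dims$d, n_heads = x$dims$n_heads,
    n_parameters = sum(vapply(x$params, length, integer(1))),
    vocab_size = vocab_size(x$vocab),
    val_loss_aa2fold = final("val_loss_AA2fold"),
    val_loss_fold2aa = final("val_loss_fold2AA"),
    val_acc_aa2fold = final("val_acc_AA2fold"),
    val_acc_fold2aa = final("val_acc_fold2AA"))
}

#' Tidy per-query benchmark sensitivities
#' @param x a `benchmark_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
#' @export
tidy.benchmark_result <- function(x, ...) x$per_query

#' Per-level benchmark summary
#' @param x a `benchmark_result`.
#' @param ... unused.
#' @exportS3Method generics::glance
#' @export
glance.benchmark_result <- function(x, ...) {
  tidyr::pivot_wider(x$summary[, c("level_name", "mean_sensitivity")],
                     names_from = "level_name",
                     values_from = "mean_sensitivity")
}

#' Tidy EAT transfers
#' @param x an `eat_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
#' @export
tidy.eat_result <- function(x, ...) x$transfers

#' Per-level EAT accuracy in one row
#' @param x an `eat_result`.
#' @param ... unused.
#' @exportS3Method generics::glance
#' @export
glance.eat_result <- function(x, ...) {
  tidyr::pivot_wider(x$accuracy[, c("level_name", "accuracy")],
                     names_from = "level_name", values_from = "accuracy")
}

#' Tidy roundtrip candidates
#' @param x a `roundtrip_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
#' @export
tidy.roundtrip_result <- function(x, ...) {
  out <- x$candidates
  out$attempt <- seq_len(nrow(out))
  out$accepted <- !is.na(x$accepted) & out$aa_seq == x$accepted
  out
}
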