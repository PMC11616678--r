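# Remote-homology benchmark statistic (per-query sensitivity up to the first
# false positive at each hierarchy level) and embedding-based annotation
# transfer (EAT) with the hierarchical correctness rule.
#
# Hierarchy labels are dot-separated strings, coarse to fine (e.g.
# "f1.s2.m1" for fold.superfamily.family); all label comparisons are
# level-prefix comparisons.

# Split dot-separated labels into a matrix of level identifiers.
hier_matrix <- function(labels) {
  parts <- strsplit(labels, ".", fixed = TRUE)
  arity <- unique(lengths(parts))
  if (length(arity) != 1) {
    stop("hierarchy labels have inconsistent arity", call. = FALSE)
  }
  matrix(unlist(parts), nrow = length(labels), byrow = TRUE,
         dimnames = list(names(labels), NULL))
}

# TRUE where a and b agree on all levels 1..level (prefix rule).
same_prefix <- function(hmat, i, j, level) {
  all(hmat[i, seq_len(level)] == hmat[j, seq_len(level)])
}

#' Sensitivity up to the first false positive for one query
#'
#' Walks the query's ranked hits best-first. A hit sharing the query's label
#' prefix down to `level` is a true positive; a hit differing already at the
#' coarsest (fold) level is a false positive and terminates the walk; hits
#' sharing the fold but differing at `level` are neutral. Returns true
#' positives found over all possible true positives at that level, or `NA`
#' if the query has no possible true positive (such queries are excluded
#' from aggregate means).
#'
#' @param hits tibble with `target_id`, `score`, sorted best-first (it is
#'   re-sorted by decreasing score defensively); must not contain the query.
#' @param query_id id of the query.
#' @param labels named character vector (or tibble with `id`, `hierarchy`)
#'   giving every protein's hierarchy label.
#' @param level 1-based level index, 1 = coarsest.
#' @return sensitivity in `[0, 1]`, or `NA_real_`.
#' @export
sensitivity_first_fp <- function(hits, query_id, labels, level) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$hierarchy, labels$id)
  }
  if (!query_id %in% names(labels)) {
    stop("query has no hierarchy label", call. = FALSE)
  }
  unlabeled <- setdiff(hits$target_id, names(labels))
  if (length(unlabeled) > 0) {
    stop("unlabeled target: ", unlabeled[1], call. = FALSE)
  }
  ids <- c(query_id, setdiff(names(labels), query_id))
  hmat <- hier_matrix(labels[ids])
  possible <- sum(vapply(2:length(ids), function(j)
    same_prefix(hmat, 1L, j, level), logical(1)))
  if (possible == 0) return(NA_real_)
  hits <- hits[order(-hits$score), ]
  tp <- 0L
  for (t in hits$target_id) {
    j <- match(t, ids)
    if (!same_prefix(hmat, 1L, j, 1L)) break        # different fold: FP
    if (same_prefix(hmat, 1L, j, level)) tp <- tp + 1L
  }
  tp / possible
}

#' Aggregate the first-FP sensitivity benchmark over all queries
#'
#' @param hitlists tibble with `query_id`, `target_id`, `score` (self-hits
#'   are dropped).
#' @param labels named character vector or tibble (`id`, `hierarchy`).
#' @param level_names optional names for the hierarchy levels (defaults to
#'   `level1..K`).
#' @return a `benchmark_result`: `per_query` (query, level, sensitivity),
#'   `summary` (per-level mean over included queries and counts), and the
#'   sorted-sensitivity curve (whose area equals the mean).
#' @export
benchmark_hitlists <- function(hitlists, labels, level_names = NULL) {
  if (nrow(hitlists) == 0) stop("empty hitlists", call. = FALSE)
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$hierarchy, labels$id)
  }
  arity <- length(strsplit(labels[[1]], ".", fixed = TRUE)[[1]])
  if (is.null(level_names)) level_names <- paste0("level", seq_len(arity))
  hitlists <- hitlists[hitlists$query_id != hitlists$target_id, ]
  per_query <- tidyr::expand_grid(
    query_id = unique(hitlists$query_id), level = seq_len(arity))
  per_query$sensitivity <- purrr::map2_dbl(
    per_query$query_id, per_query$level, function(q, lv) {
      sensitivity_first_fp(hitlists[hitlists$query_id == q, ], q, labels, lv)
    })
  per_query$level_name <- level_names[per_query$level]
  summary <- dplyr::summarise(
    dplyr::group_by(per_query, .data$level, .data$level_name),
    mean_sensitivity = mean(.data$sensitivity, na.rm = TRUE),
    n_queries = sum(!is.na(.data$sensitivity)),
    n_excluded = sum(is.na(.data$sensitivity)), .groups = "drop")
  curve <- dplyr::arrange(
    dplyr::filter(per_query, !is.na(.data$sensitivity)),
    .data$level, dplyr::desc(.data$sensitivity))
  curve <- dplyr::mutate(
    dplyr::group_by(curve, .data$level),
    query_fraction = dplyr::row_number() / dplyr::n())
  curve <- dplyr::ungroup(curve)
  structure(list(per_query = per_query, summary = summary, curve = curve),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> mean sensitivity up to the first false positive\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' All-against-all 3Di alignment search
#'
#' Builds ranked hitlists by aligning every query 3Di string against every
#' other record with [nw_align()] and ranking by alignment score; the desk
#' stand-in for a structure-alphabet search engine.
#'
#' @param records tibble with `id` and `tdi_seq` (or predicted 3Di in
#'   `tdi_seq`).
#' @param mat a 3Di [subst_matrix()].
#' @param queries optional subset of ids to use as queries (default: all).
#' @return hitlists tibble (`query_id`, `target_id`, `score`), self-hits
#'   excluded, sorted best-first within query.
#' @export
all_vs_all_3di_search <- function(records, mat, queries = NULL) {
  ids <- records$id
  if (is.null(queries)) queries <- ids
  out <- list()
  for (q in queries) {
    qs <- records$tdi_seq[match(q, ids)]
    targets <- setdiff(ids, q)
    sc <- vapply(targets, function(t)
      nw_align(qs, records$tdi_seq[match(t, ids)], mat)$score, numeric(1))
    ord <- order(-sc)
    out[[q]] <- tibble::tibble(query_id = q, target_id = targets[ord],
                               score = sc[ord])
  }
  dplyr::bind_rows(out)
}

#' Embedding-based annotation transfer (EAT)
#'
#' Transfers the full hierarchy label of the Euclidean-nearest lookup
#' protein to each query (ties broken by lookup order). Per-level accuracy
#' follows the hierarchical rule: a level is credited only if all coarser
#' levels are also correct.
#'
#' @param query_emb matrix of query embeddings (rows = queries).
#' @param query_labels true hierarchy labels of the queries (for accuracy).
#' @param lookup_emb matrix of lookup embeddings (same width).
#' @param lookup_labels hierarchy labels of the lookup rows.
#' @param level_names optional level names.
#' @return an `eat_result`: `transfers` tibble (query, nearest neighbor,
#'   distance, predicted and true labels, per-level correctness) and
#'   `accuracy` tibble per level.
#' @export
eat_transfer <- function(query_emb, query_labels, lookup_emb, lookup_labels,
                         level_names = NULL) {
  if (!is.matrix(query_emb)) query_emb <- matrix(query_emb, nrow = 1)
  if (ncol(query_emb) != ncol(lookup_emb)) {
    stop("embedding width mismatch between queries and lookup",
         call. = FALSE)
  }
  if (nrow(lookup_emb) == 0) stop("empty lookup set", call. = FALSE)
  qm <- hier_matrix(query_labels)
  lm <- hier_matrix(lookup_labels)
  arity <- ncol(qm)
  if (is.null(level_names)) level_names <- paste0("level", seq_len(arity))
  # pairwise squared Euclidean distances
  d2 <- outer(rowSums(query_emb^2), rep(1, nrow(lookup_emb))) +
    outer(rep(1, nrow(query_emb)), rowSums(lookup_emb^2)) -
    2 * tcrossprod(query_emb, lookup_emb)
  nn <- max.col(-d2, ties.method = "first")
  dist <- sqrt(pmax(0, d2[cbind(seq_len(nrow(query_emb)), nn)]))
  correct <- matrix(FALSE, nrow(query_emb), arity)
  for (lv in seq_len(arity)) {
    ok <- vapply(seq_len(nrow(query_emb)), function(i)
      all(qm[i, seq_len(lv)] == lm[nn[i], seq_len(lv)]), logical(1))
    correct[, lv] <- ok
  }
  transfers <- tibble::tibble(
    query = seq_len(nrow(query_emb)),
    neighbor = nn, distance = dist,
    predicted = lookup_labels[nn], truth = query_labels)
  for (lv in seq_len(arity)) transfers[[level_names[lv]]] <- correct[, lv]
  accuracy <- tibble::tibble(level = seq_len(arity),
                             level_name = level_names,
                             accuracy = colMeans(correct))
  structure(list(transfers = transfers, accuracy = accuracy),
            class = "eat_result")
}

#' @export
print.eat_result <- function(x, ...) {
  cat(sprintf("<eat_result> %d queries\n", nrow(x$transfers)))
  print(as.data.frame(x$accuracy), row.names = FALSE)
  invisible(x)
}
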