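# Dataset quality filters and cluster-aware train/val/test splitting.
#
# Thresholds follow the strict reading of the filter rules: records are
# removed when pLDDT < min_plddt, length < min_length, or the most frequent
# 3Di token covers MORE than max_single_token_frac of the residues; equality
# survives. A record failing several rules is counted once, under the first
# failing rule in the order (a) quality, (b) length, (c) repetitiveness.

#' Curation configuration
#'
#' @param min_plddt remove records with pLDDT strictly below this (default 70).
#' @param min_length remove records strictly shorter than this (default 30).
#' @param max_single_token_frac remove records whose single most frequent 3Di
#'   token covers strictly more than this fraction (default 0.95).
#' @param max_cluster_members diversity cap per cluster used by
#'   [cap_cluster()] (default 20).
#' @param val_size,test_size number of proteins to accumulate (as whole
#'   clusters) into the validation / test split.
#' @param seed seed for the cluster shuffle in [cluster_split()].
#' @return a `curation_config` list.
#' @export
curation_config <- function(min_plddt = 70, min_length = 30L,
                            max_single_token_frac = 0.95,
                            max_cluster_members = 20L,
                            val_size = 0L, test_size = 0L, seed = 1L) {
  stopifnot(max_single_token_frac >= 0, max_single_token_frac <= 1,
            val_size >= 0, test_size >= 0, min_length >= 0,
            max_cluster_members >= 1)
  structure(list(min_plddt = min_plddt, min_length = as.integer(min_length),
                 max_single_token_frac = max_single_token_frac,
                 max_cluster_members = as.integer(max_cluster_members),
                 val_size = as.integer(val_size),
                 test_size = as.integer(test_size),
                 seed = as.integer(seed)),
            class = "curation_config")
}

max_token_frac <- function(tdi_seq) {
  vapply(tdi_seq, function(s) {
    if (nchar(s) == 0) return(0)
    max(table(split_chars(s))) / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Apply the three dataset quality filters
#'
#' @param records tibble with `id`, `tdi_seq`, `plddt`.
#' @param cfg a [curation_config()].
#' @return list with `kept` (surviving records) and `report` (tibble of
#'   per-rule removal counts; multiply-failing records count under the first
#'   failing rule).
#' @export
apply_filters <- function(records, cfg = curation_config()) {
  if (!"plddt" %in% names(records) || anyNA(records$plddt)) {
    bad <- if (!"plddt" %in% names(records)) records$id[1] else
      records$id[which(is.na(records$plddt))[1]]
    stop(sprintf("record '%s' has no pLDDT score", bad), call. = FALSE)
  }
  if (!"tdi_seq" %in% names(records) || anyNA(records$tdi_seq)) {
    stop("records must carry 3Di sequences", call. = FALSE)
  }
  fail_a <- records$plddt < cfg$min_plddt
  fail_b <- nchar(records$tdi_seq) < cfg$min_length
  fail_c <- max_token_frac(records$tdi_seq) > cfg$max_single_token_frac
  first <- dplyr::case_when(fail_a ~ "a_low_plddt",
                            fail_b ~ "b_short",
                            fail_c ~ "c_repetitive",
                            TRUE ~ "kept")
  report <- tibble::tibble(
    rule = c("a_low_plddt", "b_short", "c_repetitive"),
    n_removed = c(sum(first == "a_low_plddt"),
                  sum(first == "b_short"),
                  sum(first == "c_repetitive")))
  list(kept = records[first == "kept", ], report = report)
}

#' Cluster-aware train/validation/test split
#'
#' Clusters are shuffled (seeded) and moved whole into the validation set
#' until at least `val_size` proteins have accumulated, then into the test
#' set until `test_size`; everything else is train. No cluster ever straddles
#' two splits. Within each validation/test cluster the member with the
#' highest pLDDT is flagged as the cluster representative, giving the
#' representatives-only view of those splits.
#'
#' @param records tibble with `cluster_id` (and `plddt` for representative
#'   selection).
#' @param cfg a [curation_config()] carrying `val_size`, `test_size`, `seed`.
#' @return the records tibble with columns `split` and `representative`
#'   (logical) rewritten.
#' @export
cluster_split <- function(records, cfg) {
  if (anyNA(records$cluster_id)) stop("all records need a cluster_id",
                                      call. = FALSE)
  clusters <- unique(records$cluster_id)
  sizes <- table(records$cluster_id)[clusters]
  order <- withr::with_seed(cfg$seed, sample(seq_along(clusters)))
  assign <- stats::setNames(rep("train", length(clusters)), clusters)
  got_val <- 0L; got_test <- 0L; i <- 1L
  while (got_val < cfg$val_size && i <= length(clusters)) {
    cl <- clusters[order[i]]
    assign[cl] <- "val"; got_val <- got_val + as.integer(sizes[cl]); i <- i + 1L
  }
  while (got_test < cfg$test_size && i <= length(clusters)) {
    cl <- clusters[order[i]]
    assign[cl] <- "test"; got_test <- got_test + as.integer(sizes[cl]); i <- i + 1L
  }
  if (got_val < cfg$val_size || got_test < cfg$test_size) {
    stop("not enough clusters to fill the requested val/test sizes",
         call. = FALSE)
  }
  out <- records
  out$split <- unname(assign[out$cluster_id])
  out <- dplyr::group_by(out, .data$cluster_id)
  out <- dplyr::mutate(out, representative = .data$split %in% c("val", "test") &
                         dplyr::row_number(dplyr::desc(.data$plddt)) == 1L)
  dplyr::ungroup(out)
}

#' Normalized amino-acid dissimilarity from a global alignment
#'
#' `1 - identities / alignment_length` under a simple match/mismatch scoring;
#' the default diversity distance for [cap_cluster()].
#'
#' @param a,b amino-acid strings.
#' @return dissimilarity in `[0, 1]`.
#' @export
aa_dissimilarity <- function(a, b) {
  mat <- aa_identity_matrix()
  aln <- nw_align(tolower(a), tolower(b), mat)
  1 - aln$pide / 100
}

# Simple AA scoring used only for the diversity distance.
aa_identity_matrix <- function() {
  alpha <- c(tolower(AA_LETTERS), "x")
  scores <- matrix(-1L, 21, 21, dimnames = list(alpha, alpha))
  diag(scores) <- 2L
  subst_matrix(alpha, scores, gap_open = -4L, gap_extend = -1L, strict = FALSE)
}

#' Cap a cluster at its k most diverse members
#'
#' Greedy max-min diversity selection: start from the representative (highest
#' pLDDT), then repeatedly add the member whose minimum distance to the
#' already selected set is largest, until `k` members are selected or the
#' cluster is exhausted.
#'
#' @param records_in_cluster tibble of one cluster's records (needs `aa_seq`,
#'   `plddt`).
#' @param k maximum members to keep (>= 1).
#' @param distance either `NULL` (use [aa_dissimilarity()]), a function of two
#'   sequences, or a symmetric numeric matrix indexed like the records.
#' @return subset of `records_in_cluster` (<= k rows, representative first).
#' @export
cap_cluster <- function(records_in_cluster, k, distance = NULL) {
  stopifnot(k >= 1)
  n <- nrow(records_in_cluster)
  if (n <= k) return(records_in_cluster)
  if (is.null(distance)) distance <- aa_dissimilarity
  D <- if (is.matrix(distance)) {
    distance
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- distance(records_in_cluster$aa_seq[i],
                                     records_in_cluster$aa_seq[j])
    }
    d
  }
  sel <- which.max(records_in_cluster$plddt)
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    min_d <- apply(D[cand, sel, drop = FALSE], 1, min)
    sel <- c(sel, cand[which.max(min_d)])
  }
  records_in_cluster[sel, ]
}
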