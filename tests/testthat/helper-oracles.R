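# Independent oracles used by property and acceptance tests.

# Exhaustive maximum over all global alignments (affine gap runs cost
# gap_open + k * gap_extend). Plain recursion over alignment paths; entirely
# independent of the Gotoh dynamic program it checks.
brute_force_nw_score <- function(a, b, mat) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  go <- mat$gap_open; ge <- mat$gap_extend
  S <- mat$scores
  rec <- function(i, j, state) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      best <- max(best, S[A[i], B[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(A)) {
      best <- max(best, ge + (if (state != "x") go else 0) +
                    rec(i + 1, j, "x"))
    }
    if (j <= length(B)) {
      best <- max(best, ge + (if (state != "y") go else 0) +
                    rec(i, j + 1, "y"))
    }
    best
  }
  rec(1, 1, "m")
}

# Second, independent implementation of sensitivity-up-to-first-FP:
# vectorized over the ranked hit labels instead of an explicit walk.
sensitivity_first_fp_alt <- function(hits, query_id, labels, level) {
  lab <- if (is.data.frame(labels)) setNames(labels$hierarchy, labels$id)
         else labels
  split_lv <- function(x, k) {
    vapply(strsplit(x, ".", fixed = TRUE),
           function(p) paste(p[seq_len(k)], collapse = "."), character(1))
  }
  q_fold <- split_lv(lab[query_id], 1)
  q_pref <- split_lv(lab[query_id], level)
  others <- lab[setdiff(names(lab), query_id)]
  possible <- sum(split_lv(others, level) == q_pref)
  if (possible == 0) return(NA_real_)
  hl <- lab[hits$target_id[order(-hits$score)]]
  is_fp <- split_lv(hl, 1) != q_fold
  cutoff <- if (any(is_fp)) which(is_fp)[1] - 1 else length(hl)
  sum(split_lv(hl[seq_len(cutoff)], level) == q_pref) / possible
}

# Independent re-derivation of the processed next-token distribution from the
# stated rules (penalty -> temperature -> top-k -> top-p -> softmax), written
# as straight-line scalar code so it shares nothing with process_logits.
oracle_processed_probs <- function(logits, generated, cfg) {
  z <- logits
  for (t in unique(generated)) {
    z[t] <- if (z[t] > 0) z[t] / cfg$repetition_penalty
            else z[t] * cfg$repetition_penalty
  }
  z <- z / cfg$temperature
  keep <- rep(TRUE, length(z))
  if (cfg$top_k > 0 && cfg$top_k < length(z)) {
    ord <- order(z, decreasing = TRUE)       # ties: lower index first
    keep <- seq_along(z) %in% ord[seq_len(cfg$top_k)]
  }
  if (cfg$top_p < 1) {
    pk <- exp(z) * keep
    pk <- pk / sum(pk)
    ord <- order(pk, decreasing = TRUE)
    cum <- 0; nucleus <- c()
    for (i in ord) {
      if (pk[i] == 0) break
      nucleus <- c(nucleus, i)
      cum <- cum + pk[i]
      if (cum >= cfg$top_p - 1e-12) break
    }
    keep <- keep & seq_along(z) %in% nucleus
  }
  p <- exp(z) * keep
  p / sum(p)
}

hier_prefix <- function(labels, lv) {
  vapply(strsplit(labels, ".", fixed = TRUE),
         function(p) paste(p[seq_len(lv)], collapse = "."), character(1))
}

# Random hitlist + label universe generator for the benchmark properties.
random_label_universe <- function(n, seed) {
  withr::with_seed(seed, {
    ids <- paste0("x", seq_len(n))
    labs <- paste0("f", sample(1:3, n, TRUE))
    labs <- paste0(labs, ".s", sample(1:2, n, TRUE))
    labs <- paste0(labs, ".m", sample(1:2, n, TRUE))
    setNames(labs, ids)
  })
}
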