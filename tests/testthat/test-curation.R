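make_rec <- function(id, plddt, len, tdi = NULL, cluster = "c1") {
  tibble::tibble(id = id, aa_seq = strrep("A", len),
                 tdi_seq = if (is.null(tdi))
                   paste(rep(TDI_LETTERS, length.out = len), collapse = "")
                 else tdi,
                 plddt = plddt, cluster_id = cluster)
}

test_that("filters use strict thresholds: equality survives, violation removes", {
  recs <- dplyr::bind_rows(
    make_rec("low_plddt", 69.9, 100),
    make_rec("edge_plddt", 70.0, 100),
    make_rec("short", 90, 29),
    make_rec("edge_len", 90, 30),
    make_rec("repetitive", 90, 100,
             paste0(strrep("v", 96), "acde")),        # 0.96 > 0.95
    make_rec("edge_rep", 90, 100,
             paste0(strrep("v", 95), "acdef")))       # exactly 0.95
  out <- apply_filters(recs, curation_config())
  expect_setequal(out$kept$id, c("edge_plddt", "edge_len", "edge_rep"))
  rep_counts <- setNames(out$report$n_removed, out$report$rule)
  expect_equal(unname(rep_counts["a_low_plddt"]), 1)
  expect_equal(unname(rep_counts["b_short"]), 1)
  expect_equal(unname(rep_counts["c_repetitive"]), 1)
})

test_that("a record failing several rules counts once, under the first rule", {
  recs <- make_rec("doubly_bad", 50, 20)   # fails (a) and (b)
  out <- apply_filters(recs, curation_config())
  expect_equal(out$report$n_removed, c(1, 0, 0))
})

test_that("missing pLDDT is an error naming the record", {
  recs <- make_rec("nameless", NA_real_, 50)
  expect_error(apply_filters(recs, curation_config()), "nameless")
})

test_that("filter pass-rate is monotone non-increasing in both thresholds", {
  w <- generate_world(world_config(n_proteins = 250, seed = 21))
  kept <- function(minp, minl) {
    nrow(apply_filters(w, curation_config(min_plddt = minp,
                                          min_length = minl))$kept)
  }
  ks <- vapply(c(0, 50, 70, 85, 101), kept, numeric(1), minl = 30)
  expect_true(all(diff(ks) <= 0))
  kl <- vapply(c(0, 30, 45, 61), kept, numeric(1), minp = 0)
  expect_true(all(diff(kl) <= 0))
})

test_that("cluster split assigns whole clusters; the {5,3,2} worked example", {
  recs <- dplyr::bind_rows(
    make_rec(paste0("a", 1:5), 80 + 1:5, 50, cluster = "cA"),
    make_rec(paste0("b", 1:3), 80 + 1:3, 50, cluster = "cB"),
    make_rec(paste0("c", 1:2), 80 + 1:2, 50, cluster = "cC"))
  out <- cluster_split(recs, curation_config(val_size = 2, test_size = 2,
                                             seed = 7))
  tab <- table(out$cluster_id, out$split)
  # each cluster fully in one split
  expect_true(all(rowSums(tab > 0) == 1))
  # val and test each hold exactly one whole cluster (every size >= 2)
  expect_equal(length(unique(out$cluster_id[out$split == "val"])), 1)
  expect_equal(length(unique(out$cluster_id[out$split == "test"])), 1)
  # representatives-only views hold one record each: the highest-pLDDT member
  for (sp in c("val", "test")) {
    reps <- out[out$split == sp & out$representative, ]
    expect_equal(nrow(reps), 1)
    members <- out[out$split == sp, ]
    expect_equal(reps$plddt, max(members$plddt))
  }
})

test_that("val_size = test_size = 0 leaves everything in train", {
  recs <- make_rec(paste0("r", 1:6), 80, 40, cluster = "c1")
  out <- cluster_split(recs, curation_config(val_size = 0, test_size = 0))
  expect_true(all(out$split == "train"))
})

test_that("split is deterministic given seed and errors when clusters run out", {
  w <- generate_world(world_config(n_proteins = 200, seed = 30))
  cfg <- curation_config(val_size = 30, test_size = 30, seed = 4)
  expect_identical(cluster_split(w, cfg), cluster_split(w, cfg))
  expect_error(cluster_split(w, curation_config(val_size = 150,
                                                test_size = 100)),
               "not enough clusters")
})

test_that("cap_cluster does greedy max-min selection from the representative", {
  # 1-D toy: points at 0, 1, 2, 10; representative (highest pLDDT) at 0
  recs <- tibble::tibble(id = paste0("p", 1:4),
                         aa_seq = strrep("A", 10),
                         plddt = c(99, 80, 81, 82), cluster_id = "c")
  D <- abs(outer(c(0, 1, 2, 10), c(0, 1, 2, 10), "-"))
  out <- cap_cluster(recs, 3, distance = D)
  expect_equal(out$id, c("p1", "p4", "p3"))   # {0, 10, then 2: min-dist 2 > 1}
  expect_equal(cap_cluster(recs, 1, distance = D)$id, "p1")
  expect_identical(cap_cluster(recs, 10, distance = D), recs)
})

test_that("the default diversity distance is alignment-based dissimilarity", {
  expect_equal(aa_dissimilarity("ACDE", "ACDE"), 0)
  expect_gt(aa_dissimilarity("ACDE", "WWWW"), 0.9)
})
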