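demo_labels <- c(
  q   = "f1.s1.m1",
  t1  = "f1.s1.m1", t2 = "f1.s1.m1", t3 = "f1.s1.m1", t4 = "f1.s1.m1",
  n1  = "f1.s2.m1",                       # same fold, different family
  fp1 = "f2.s1.m1", fp2 = "f2.s1.m2")

hits_of <- function(targets) {
  tibble::tibble(target_id = targets,
                 score = rev(seq_along(targets)))
}

test_that("sensitivity walk reproduces the hand-derived cases", {
  lv_family <- 3
  # all TPs precede any FP
  expect_equal(sensitivity_first_fp(hits_of(c("t1", "t2", "t3", "t4", "fp1")),
                                    "q", demo_labels, lv_family), 1.0)
  # first hit is a different-fold FP
  expect_equal(sensitivity_first_fp(hits_of(c("fp1", "t1", "t2")),
                                    "q", demo_labels, lv_family), 0.0)
  # [TP, neutral, TP, FP, TP] with 4 possible -> 2/4
  expect_equal(sensitivity_first_fp(hits_of(c("t1", "n1", "t2", "fp1", "t3")),
                                    "q", demo_labels, lv_family), 0.5)
})

test_that("neutral hits are transparent: permuting them never changes sensitivity", {
  labels <- random_label_universe(30, seed = 41)
  q <- names(labels)[1]
  withr::with_seed(42, {
    for (rep in 1:20) {
      targets <- sample(setdiff(names(labels), q), 20)
      base <- sensitivity_first_fp(hits_of(targets), q, labels, 2)
      # permute the neutral hits among their own positions
      q_parts <- strsplit(labels[q], ".", fixed = TRUE)[[1]]
      is_neutral <- vapply(targets, function(t) {
        p <- strsplit(labels[t], ".", fixed = TRUE)[[1]]
        p[1] == q_parts[1] && !all(p[1:2] == q_parts[1:2])
      }, logical(1))
      perm <- targets
      perm[is_neutral] <- sample(targets[is_neutral])
      expect_equal(sensitivity_first_fp(hits_of(perm), q, labels, 2), base)
    }
  })
})

test_that("the walk agrees with an independent second implementation", {
  withr::with_seed(77, {
    for (rep in 1:60) {
      labels <- random_label_universe(15, seed = sample.int(1e6, 1))
      q <- sample(names(labels), 1)
      targets <- sample(setdiff(names(labels), q),
                        sample(3:14, 1))
      hits <- tibble::tibble(target_id = targets,
                             score = stats::rnorm(length(targets)))
      for (lv in 1:3) {
        expect_equal(sensitivity_first_fp(hits, q, labels, lv),
                     sensitivity_first_fp_alt(hits, q, labels, lv))
      }
    }
  })
})

test_that("unlabeled targets are an error; zero-TP queries are excluded as NA", {
  labels <- c(q = "f1.s1.m1", a = "f2.s1.m1")
  expect_error(sensitivity_first_fp(hits_of("zzz"), "q", labels, 1),
               "unlabeled")
  # no other member shares q's fold -> no possible TP at any level
  expect_true(is.na(sensitivity_first_fp(hits_of("a"), "q", labels, 1)))
})

test_that("benchmark aggregates per-query sensitivities and is deterministic", {
  # two families in the same fold universe; each query's only possible TP is
  # its own family partner
  labels <- c(q1 = "f1.s1.m1", t1 = "f1.s1.m1",
              q2 = "f2.s1.m1", t2 = "f2.s1.m1")
  hits <- dplyr::bind_rows(
    tibble::tibble(query_id = "q1", target_id = c("t1", "q2"),
                   score = c(2, 1)),
    tibble::tibble(query_id = "q2", target_id = c("t1", "t2"),
                   score = c(2, 1)))
  res <- benchmark_hitlists(hits, labels)
  # q1 finds its TP first (1.0), q2 hits the FP first (0.0) -> mean 0.5
  expect_equal(res$summary$mean_sensitivity, rep(0.5, 3))
  expect_identical(res, benchmark_hitlists(hits, labels))
  # curve area equals the mean
  lv1 <- res$curve[res$curve$level == 1, ]
  expect_equal(mean(lv1$sensitivity), 0.5)
  expect_error(benchmark_hitlists(hits[0, ], labels), "empty")
})

test_that("alignment-score hitlists beat random scores on the clean world", {
  w <- generate_world(world_config(n_proteins = 120, noise_rate = 0,
                                   seed = 55))
  sub <- w[1:70, ]
  mat <- synthetic_3di_matrix()
  queries <- sub$id[1:50]
  hits_aln <- all_vs_all_3di_search(sub, mat, queries = queries)
  labels <- setNames(sub$hierarchy, sub$id)
  res_aln <- benchmark_hitlists(hits_aln, labels)
  withr::with_seed(3, {
    hits_rnd <- dplyr::mutate(hits_aln, score = stats::rnorm(dplyr::n()))
  })
  res_rnd <- benchmark_hitlists(hits_rnd, labels)
  for (lv in 1:3) {
    expect_gt(res_aln$summary$mean_sensitivity[lv],
              res_rnd$summary$mean_sensitivity[lv])
  }
})

test_that("EAT transfers the nearest neighbor's full label", {
  lookup <- rbind(c(0, 0), c(10, 0), c(0, 10))
  lookup_labels <- c("f1.s1.m1", "f2.s1.m1", "f1.s2.m2")
  res <- eat_transfer(rbind(c(0.1, 0)), "f1.s1.m1", lookup, lookup_labels)
  expect_equal(res$transfers$neighbor, 1)
  expect_equal(res$transfers$predicted, "f1.s1.m1")
  expect_equal(res$accuracy$accuracy, c(1, 1, 1))
  # exact match has distance 0
  res0 <- eat_transfer(rbind(c(10, 0)), "f2.s1.m1", lookup, lookup_labels)
  expect_equal(res0$transfers$distance, 0)
})

test_that("hierarchical credit requires all coarser levels to be correct", {
  lookup <- rbind(c(0, 0))
  # neighbor correct at levels 1-2 but wrong at 3
  res <- eat_transfer(rbind(c(0, 0)), "f1.s1.m1", lookup, "f1.s1.m9")
  expect_equal(res$accuracy$accuracy, c(1, 1, 0))
  # wrong at level 2: level 3 cannot be credited even if it matches textually
  res2 <- eat_transfer(rbind(c(0, 0)), "f1.s1.m1", lookup, "f1.s9.m1")
  expect_equal(res2$accuracy$accuracy, c(1, 0, 0))
})

test_that("per-level EAT accuracy is non-increasing from coarse to fine", {
  withr::with_seed(91, {
    for (rep in 1:10) {
      n <- 40
      emb_q <- matrix(rnorm(2 * n), n, 2)
      emb_l <- matrix(rnorm(2 * n), n, 2)
      labels <- random_label_universe(2 * n, seed = sample.int(1e6, 1))
      res <- eat_transfer(emb_q, labels[1:n], emb_l, labels[(n + 1):(2 * n)])
      expect_true(all(diff(res$accuracy$accuracy) <= 1e-12))
    }
  })
  expect_error(eat_transfer(matrix(0, 1, 3), "f1.s1.m1",
                            matrix(0, 1, 2), "f1.s1.m1"),
               "width mismatch")
})
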