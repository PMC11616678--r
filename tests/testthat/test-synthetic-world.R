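test_that("world generation is deterministic given the seed", {
  cfg <- world_config(n_proteins = 60, seed = 9)
  expect_identical(generate_world(cfg), generate_world(cfg))
  cfg2 <- world_config(n_proteins = 60, seed = 10)
  expect_false(identical(generate_world(cfg), generate_world(cfg2)))
})

test_that("at zero noise the structure string is the deterministic local map", {
  w <- generate_world(world_config(n_proteins = 40, noise_rate = 0, seed = 4))
  recomputed <- vapply(w$aa_seq, apply_structure_map, character(1),
                       USE.NAMES = FALSE)
  expect_identical(w$tdi_seq, recomputed)
  expect_equal(nchar(w$aa_seq), nchar(w$tdi_seq))
})

test_that("token distribution is skewed: top-3 tokens cover over half of residues", {
  w <- generate_world(world_config(n_proteins = 300, noise_rate = 0, seed = 4))
  tok <- unlist(strsplit(paste(w$tdi_seq, collapse = ""), ""))
  expect_gte(length(tok), 10000)
  freq <- sort(table(tok) / length(tok), decreasing = TRUE)
  expect_gte(sum(freq[1:3]), 0.5)
})

test_that("noise destroys the AA/3Di dependence (mutual-information contrast)", {
  # conditional accuracy of the map: exact at noise 0, near chance at noise 1
  w0 <- generate_world(world_config(n_proteins = 80, noise_rate = 0, seed = 6))
  w1 <- generate_world(world_config(n_proteins = 80, noise_rate = 1, seed = 6))
  agree <- function(w) {
    g <- vapply(w$aa_seq, apply_structure_map, character(1), USE.NAMES = FALSE)
    mean(unlist(strsplit(g, "")) == unlist(strsplit(w$tdi_seq, "")))
  }
  expect_equal(agree(w0), 1)
  # at full noise agreement equals the chance of the noise draw matching g:
  # bounded well below the skewed-map self-agreement
  expect_lt(agree(w1), 0.15)
})

test_that("same-family pairs are more sequence-similar than cross-family pairs", {
  w <- generate_world(world_config(n_proteins = 120, seed = 8))
  fams <- split(seq_len(nrow(w)), w$hierarchy)
  ident <- function(i, j) 1 - aa_dissimilarity(w$aa_seq[i], w$aa_seq[j])
  withr::with_seed(1, {
    same <- replicate(40, { f <- sample(fams, 1)[[1]]
      p <- sample(f, 2); ident(p[1], p[2]) })
    cross <- replicate(40, { p <- sample(nrow(w), 2)
      while (w$hierarchy[p[1]] == w$hierarchy[p[2]]) p <- sample(nrow(w), 2)
      ident(p[1], p[2]) })
  })
  expect_gt(mean(same), mean(cross) + 0.1)
})

test_that("pLDDT scores live in [40, 100] with a controllable low tail", {
  w <- generate_world(world_config(n_proteins = 800, low_plddt_frac = 0.2,
                                   seed = 3))
  expect_true(all(w$plddt >= 40 & w$plddt <= 100))
  expect_gt(mean(w$plddt < 70), 0.08)
  expect_lt(mean(w$plddt < 70), 0.32)
  w2 <- generate_world(world_config(n_proteins = 800, low_plddt_frac = 0,
                                    seed = 3))
  expect_lt(mean(w2$plddt < 70), 0.05)
})

test_that("hierarchy and clusters have the configured shape, clusters nested in families", {
  w <- generate_world(world_config(n_proteins = 400,
                                   hierarchy_shape = c(3, 2, 2),
                                   n_clusters = 48, seed = 5))
  expect_equal(length(unique(w$hierarchy)), 12)
  expect_true(all(grepl("^f\\d+\\.s\\d+\\.m\\d+$", w$hierarchy)))
  nested <- tapply(w$hierarchy, w$cluster_id, function(h) length(unique(h)))
  expect_true(all(nested == 1))
})

test_that("the DSSP 8-to-3-state mapping follows the standard convention", {
  expect_equal(dssp8_to_ss3("GHIBE-TS"), "HHHEEOOO")
})

test_that("ss3 co-occurrence rows are proportions over helix/strand/other", {
  w <- generate_world(world_config(n_proteins = 150, seed = 12))
  ss3 <- synthetic_ss3(w, flip_rate = 0.1, seed = 1)
  co <- ss3_cooccurrence(w, ss3)
  rs <- rowSums(co$props[rowSums(co$counts) > 0, , drop = FALSE])
  expect_equal(unname(rs), rep(1, length(rs)))
  expect_equal(sum(co$counts), sum(nchar(w$tdi_seq)))
  # the generator's design: v prefers helix, e prefers strand
  expect_equal(unname(colnames(co$props)[which.max(co$props["v", ])]), "H")
  expect_equal(unname(colnames(co$props)[which.max(co$props["e", ])]), "E")

  # an all-helix token row is (1, 0, 0)
  one <- tibble::tibble(id = "t", tdi_seq = "vvvv")
  co1 <- ss3_cooccurrence(one, "HHHH")
  expect_equal(unname(co1$props["v", ]), c(1, 0, 0))

  # uniform labels give rows near (1/3, 1/3, 1/3)
  withr::with_seed(2, {
    unif <- vapply(w$tdi_seq, function(s)
      paste(sample(c("H", "E", "O"), nchar(s), TRUE), collapse = ""),
      character(1), USE.NAMES = FALSE)
  })
  cou <- ss3_cooccurrence(w, unif)
  busy <- rowSums(cou$counts) > 300
  expect_true(all(abs(cou$props[busy, ] - 1 / 3) < 0.12))

  expect_error(ss3_cooccurrence(one, "HHH"), "length mismatch")
})
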