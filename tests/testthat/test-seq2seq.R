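test_that("span corruption is exactly invertible and orders sentinels", {
  v <- toy_vocab()
  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(5:120, 1)
      ids <- vocab_encode(v, paste(sample(AA_LETTERS, n, TRUE), collapse = ""),
                          "none", add_eos = FALSE)
      cs <- span_corrupt(ids, v, rate = 0.15, mean_span = 3)
      expect_identical(reconstruct_corruption(cs, v), ids)
      # sentinels appear in the same order in input and target
      in_sent <- cs$input_ids[cs$input_ids %in% v$sentinel_ids]
      tg_sent <- cs$target_ids[cs$target_ids %in% v$sentinel_ids]
      expect_identical(in_sent, tg_sent)
    }
  })
})

test_that("zero corruption leaves the input unchanged", {
  v <- toy_vocab()
  ids <- vocab_encode(v, "ACDEF", "none", add_eos = FALSE)
  cs <- span_corrupt(ids, v, rate = 0.05, mean_span = 3)  # round(0.25) = 0
  expect_identical(cs$input_ids, c(ids, v$eos_id))
  expect_identical(cs$target_ids, c(v$sentinel_ids[1], v$eos_id))
})

test_that("masked fraction concentrates on the corruption rate", {
  v <- toy_vocab()
  withr::with_seed(23, {
    fr <- replicate(400, {
      ids <- sample(v$aa_ids, 100, TRUE)
      span_corrupt(ids, v, rate = 0.15, mean_span = 3)$masked_fraction
    })
  })
  expect_gte(mean(fr), 0.13)
  expect_lte(mean(fr), 0.17)
})

test_that("more spans than sentinels is an error", {
  v <- bilingual_vocab(n_sentinel = 2)
  ids <- rep(v$aa_ids[1:10], 20)
  expect_error(span_corrupt(ids, v, rate = 0.5, mean_span = 1), "sentinel")
  expect_error(span_corrupt(c(v$sentinel_ids[1], v$aa_ids[1]), v),
               "already contain sentinels")
})

test_that("translation batches carry prefixes, truncation and both directions", {
  v <- toy_vocab()
  rec <- tibble::tibble(aa_seq = strrep("A", 300),
                        tdi_seq = strrep("v", 300))
  both <- make_translation_batch(rec, "both", max_len = 256, vocab = v)
  expect_length(both, 2)
  # truncated to 256 residues: prefix + 256 + EOS on the encoder side
  expect_length(both[[1]]$enc_ids, 258)
  expect_length(both[[1]]$dec_tgt_ids, 257)
  expect_equal(both[[1]]$enc_ids[1], v$prefix_ids[1])
  expect_equal(both[[2]]$enc_ids[1], v$prefix_ids[2])
  # decoder input is the target shifted right behind the pad start
  expect_equal(both[[1]]$dec_in_ids[1], v$pad_id)
  expect_equal(both[[1]]$dec_in_ids[-1],
               both[[1]]$dec_tgt_ids[-length(both[[1]]$dec_tgt_ids)])

  unpaired <- tibble::tibble(aa_seq = "ACD", tdi_seq = NA_character_)
  expect_error(make_translation_batch(unpaired, "AA2fold", 256, v),
               "unpaired")
})

test_that("hand-written backprop matches finite differences", {
  v <- bilingual_vocab(4)
  cfg <- list(n_layers = 1, d = 8, n_heads = 2)
  p <- foldlingo:::init_params(foldlingo:::vocab_size(v), 8, 1, 2, seed = 3)
  enc <- list(vocab_encode(v, "ACDE", "AA2fold"),
              vocab_encode(v, "vvd", "fold2AA"))
  tgt <- list(vocab_encode(v, "vvda"), vocab_encode(v, "ACD"))
  din <- lapply(tgt, function(t) c(0L, t[-length(t)]))
  r <- foldlingo:::seq2seq_loss(p, cfg, enc, din, tgt)
  eps <- 1e-5
  withr::with_seed(1, {
    for (nm in ls(r$grads)) {
      idx <- sample(length(p[[nm]]), min(3, length(p[[nm]])))
      for (i in idx) {
        p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
        lp <- foldlingo:::seq2seq_loss(p2, cfg, enc, din, tgt,
                                       want_grads = FALSE)$loss
        p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
        lm <- foldlingo:::seq2seq_loss(p2, cfg, enc, din, tgt,
                                       want_grads = FALSE)$loss
        num <- (lp - lm) / (2 * eps)
        expect_equal(r$grads[[nm]][i], num, tolerance = 1e-4,
                     info = nm)
      }
    }
  })
})

test_that("a short training run decreases denoising and translation loss", {
  w <- generate_world(world_config(n_proteins = 200, noise_rate = 0,
                                   seed = 19))
  w <- cluster_split(w, curation_config(val_size = 30, test_size = 0,
                                        seed = 1))
  cfg <- train_config(steps = 16, phase2_max_len_schedule = list(c(30L, 64L)),
                      batch_size = 8, val_every = 0, seed = 2,
                      model_dims = c(1L, 32L, 2L))
  m <- train_translation_model(w, cfg, vocab = toy_vocab(), quiet = TRUE)
  tr <- tidy(m)
  p1 <- tr$value[tr$phase == "denoise" & grepl("train_loss", tr$metric)]
  p2 <- tr$value[tr$phase == "translate" & grepl("train_loss", tr$metric)]
  expect_lt(mean(utils::tail(p1, 4)), mean(utils::head(p1, 4)))
  expect_lt(mean(utils::tail(p2, 6)), mean(utils::head(p2, 6)))
  # denoising-only exposure keeps both modalities at finite loss
  for (mo in c("AA2fold", "fold2AA")) {
    ev <- teacher_forced_eval(m, w[w$split == "val", ], mo, max_records = 10)
    expect_true(is.finite(ev$loss))
  }
  expect_error(train_translation_model(w[w$split == "train", ], cfg,
                                       toy_vocab()),
               "empty validation split")
})

test_that("encoder embeddings are per-residue, deterministic, and pool to width", {
  w <- generate_world(world_config(n_proteins = 5, seed = 25))
  cfg <- train_config(steps = 2, phase2_max_len_schedule = list(c(2L, 64L)),
                      batch_size = 4, val_every = 0, seed = 2,
                      model_dims = c(1L, 32L, 2L))
  w$split <- c("val", rep("train", 4))
  m <- train_translation_model(w, cfg, vocab = toy_vocab(), quiet = TRUE)
  e1 <- encoder_embed(m, w$aa_seq[1])
  expect_equal(nrow(e1), nchar(w$aa_seq[1]))
  expect_equal(ncol(e1), 32)
  expect_identical(e1, encoder_embed(m, w$aa_seq[1]))
  expect_length(mean_pool(e1), 32)
  e3 <- encoder_embed(m, w$tdi_seq[2])      # 3Di input infers fold2AA prefix
  expect_equal(nrow(e3), nchar(w$tdi_seq[2]))
})

test_that("model checkpoints round-trip through disk", {
  w <- generate_world(world_config(n_proteins = 6, seed = 26))
  w$split <- c("val", rep("train", 5))
  cfg <- train_config(steps = 2, phase2_max_len_schedule = list(c(2L, 64L)),
                      batch_size = 4, val_every = 0, seed = 2,
                      model_dims = c(1L, 32L, 2L))
  m <- train_translation_model(w, cfg, vocab = toy_vocab(), quiet = TRUE)
  dir <- tempfile()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(m$params, m2$params)
  expect_identical(translate(m, "ACDEF", "AA2fold", decode_config(seed = 1)),
                   translate(m2, "ACDEF", "AA2fold", decode_config(seed = 1)))
})
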