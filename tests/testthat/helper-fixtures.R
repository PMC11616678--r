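# Shared fixtures. Expensive artifacts (the trained toy model and its world)
# are built once per test run and memoized here so every test file can reuse
# them.

fixture_env <- new.env(parent = emptyenv())

toy_vocab <- function(n_sentinel = 16) bilingual_vocab(n_sentinel)

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# The noise-free study world: >= 5k paired sequences, cluster-aware split.
get_clean_world <- function() {
  if (is.null(fixture_env$world)) {
    w <- generate_world(world_config(n_proteins = 5000, noise_rate = 0,
                                     seed = 11))
    w <- cluster_split(w, curation_config(val_size = 150, test_size = 150,
                                          seed = 2))
    fixture_env$world <- w
  }
  fixture_env$world
}

# Toy translation model trained on the noise-free world (several minutes of
# CPU; shared by the end-to-end, structure-head, embedding and roundtrip
# tests).
get_toy_model <- function() {
  if (is.null(fixture_env$model)) {
    w <- get_clean_world()
    cfg <- train_config(steps = 60,
                        phase2_max_len_schedule = list(c(2400L, 256L)),
                        phase1_lr = 1e-3, phase2_lr = 2e-3,
                        batch_size = 16, val_every = 600, seed = 5,
                        model_dims = c(2L, 64L, 4L))
    fixture_env$model <- train_translation_model(w, cfg,
                                                 vocab = toy_vocab(),
                                                 quiet = TRUE)
  }
  fixture_env$model
}

# Structure head trained on frozen encoder embeddings of the toy model.
get_toy_head <- function() {
  if (is.null(fixture_env$head)) {
    w <- get_clean_world()
    model <- get_toy_model()
    train_recs <- w[w$split == "train", ][1:400, ]
    emb <- lapply(train_recs$aa_seq, function(s)
      encoder_embed(model, s, "AA2fold"))
    fixture_env$head <- train_head(emb, train_recs$tdi_seq,
                                   head_config(epochs = 10, seed = 3),
                                   quiet = TRUE)
  }
  fixture_env$head
}

# Noise-only world and model: the negative control.
get_noise_model <- function() {
  if (is.null(fixture_env$noise_model)) {
    w <- generate_world(world_config(n_proteins = 1000, noise_rate = 1,
                                     seed = 13))
    w <- cluster_split(w, curation_config(val_size = 120, test_size = 0,
                                          seed = 2))
    cfg <- train_config(steps = 20,
                        phase2_max_len_schedule = list(c(280L, 256L)),
                        phase1_lr = 1e-3, phase2_lr = 2e-3,
                        batch_size = 16, val_every = 0, seed = 5,
                        model_dims = c(2L, 64L, 4L))
    fixture_env$noise_world <- w
    fixture_env$noise_model <- train_translation_model(w, cfg,
                                                       vocab = toy_vocab(),
                                                       quiet = TRUE)
  }
  fixture_env$noise_model
}

get_noise_world <- function() {
  get_noise_model()
  fixture_env$noise_world
}
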