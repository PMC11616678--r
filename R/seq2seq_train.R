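# Training objectives and the two-phase schedule: span-corruption denoising
# on both modalities (phase 1), then bidirectional translation with direction
# prefixes (phase 2, with a max-length curriculum).

#' Training configuration for the translation model
#'
#' The two-phase structure mirrors the published recipe (denoising at a
#' higher learning rate, then translation at a lower one, with the maximum
#' sequence length raised mid-phase); magnitudes are scaled to a from-scratch
#' desk-size model. `steps` counts phase-1 steps; phase-2 length is the sum
#' of steps in `phase2_max_len_schedule`.
#'
#' @param phase1_lr,phase2_lr Adam learning rates for the two phases.
#' @param phase1_max_len maximum residues per sequence in phase 1 (longer
#'   sequences are truncated).
#' @param phase2_max_len_schedule list of `c(steps, max_len)` segments.
#' @param batch_size sequences per optimizer micro-batch.
#' @param grad_accum micro-batches accumulated per optimizer step.
#' @param corruption_rate expected fraction of tokens masked by span
#'   corruption.
#' @param mean_span_len mean masked-span length.
#' @param steps phase-1 (denoising) steps.
#' @param val_every validation cadence in steps (0 = only at phase ends).
#' @param val_max_records validation subsample size per evaluation.
#' @param seed seed controlling init, batch order and corruption.
#' @param model_dims integer triple `(layers, width, heads)`.
#' @return a `train_config` list.
#' @export
train_config <- function(phase1_lr = 1e-3, phase2_lr = 3e-4,
                         phase1_max_len = 256L,
                         phase2_max_len_schedule = list(c(300L, 256L),
                                                        c(1800L, 512L)),
                         batch_size = 16L, grad_accum = 1L,
                         corruption_rate = 0.15, mean_span_len = 3,
                         steps = 300L, val_every = 100L,
                         val_max_records = 48L, seed = 1L,
                         model_dims = c(2L, 128L, 4L)) {
  stopifnot(phase1_lr > 0, phase2_lr > 0, phase1_max_len >= 1,
            batch_size >= 1, grad_accum >= 1,
            corruption_rate > 0, corruption_rate < 1, mean_span_len >= 1,
            steps >= 0, length(model_dims) == 3, all(model_dims >= 1),
            model_dims[2] %% model_dims[3] == 0)
  structure(list(phase1_lr = phase1_lr, phase2_lr = phase2_lr,
                 phase1_max_len = as.integer(phase1_max_len),
                 phase2_max_len_schedule = phase2_max_len_schedule,
                 batch_size = as.integer(batch_size),
                 grad_accum = as.integer(grad_accum),
                 corruption_rate = corruption_rate,
                 mean_span_len = mean_span_len,
                 steps = as.integer(steps),
                 val_every = as.integer(val_every),
                 val_max_records = as.integer(val_max_records),
                 seed = as.integer(seed),
                 model_dims = as.integer(model_dims)),
            class = "train_config")
}

# Uniform random composition of total into k positive parts.
rand_composition <- function(total, k) {
  if (k == 1) return(total)
  cuts <- sort(sample.int(total - 1L, k - 1L))
  diff(c(0L, cuts, total))
}

#' Span-corrupt a token id sequence
#'
#' Replaces contiguous spans with sentinel ids in the input and emits the
#' dropped spans, each introduced by its sentinel, as the target. The number
#' of masked tokens is `round(rate * length)`, split into approximately
#' `masked / mean_span` spans whose lengths are drawn as a uniform random
#' composition (geometric-like); spans are separated by at least one kept
#' token so reconstruction is exact.
#'
#' @param ids integer vector of content token ids (no sentinels, no EOS).
#' @param vocab a [bilingual_vocab()].
#' @param rate target corrupted fraction.
#' @param mean_span mean span length.
#' @return a `corruption_sample`: `input_ids` (ends with EOS), `target_ids`
#'   (sentinel-delimited spans, ends with EOS), `masked_fraction`.
#' @export
span_corrupt <- function(ids, vocab, rate = 0.15, mean_span = 3) {
  ids <- as.integer(ids)
  if (any(ids %in% vocab$sentinel_ids)) {
    stop("input ids already contain sentinels", call. = FALSE)
  }
  n <- length(ids)
  m <- round(rate * n)
  if (m < 1) {
    return(structure(list(
      input_ids = c(ids, vocab$eos_id),
      target_ids = c(vocab$sentinel_ids[1], vocab$eos_id),
      masked_fraction = 0), class = "corruption_sample"))
  }
  k <- max(1L, min(round(m / mean_span), m, floor((n - m) + 1L)))
  if (k > length(vocab$sentinel_ids)) {
    stop(sprintf("%d spans exceed the %d available sentinels", k,
                 length(vocab$sentinel_ids)), call. = FALSE)
  }
  span_lens <- rand_composition(m, k)
  # gaps: k+1 runs of kept tokens; interior gaps >= 1 to keep spans separate
  n_keep <- n - m
  gap_lens <- if (k == 1) {
    g <- rand_composition(n_keep + 2L, 2L) - 1L
    c(g[1], g[2])
  } else {
    g <- rand_composition(n_keep + 2L, k + 1L)
    c(g[1] - 1L, g[2:k], g[k + 1] - 1L)
  }
  input <- integer(0); target <- integer(0); pos <- 1L
  for (i in seq_len(k)) {
    keep <- gap_lens[i]
    if (keep > 0) input <- c(input, ids[pos:(pos + keep - 1L)])
    pos <- pos + keep
    sp <- span_lens[i]
    input <- c(input, vocab$sentinel_ids[i])
    target <- c(target, vocab$sentinel_ids[i], ids[pos:(pos + sp - 1L)])
    pos <- pos + sp
  }
  if (gap_lens[k + 1] > 0) input <- c(input, ids[pos:(pos + gap_lens[k + 1] - 1L)])
  structure(list(
    input_ids = c(input, vocab$eos_id),
    target_ids = c(target, vocab$eos_id),
    masked_fraction = m / n), class = "corruption_sample")
}

#' Invert a span-corruption sample
#'
#' @param sample a `corruption_sample` (or a list with `input_ids`,
#'   `target_ids`).
#' @param vocab the vocabulary used for corruption.
#' @return the original content id vector.
#' @export
reconstruct_corruption <- function(sample, vocab) {
  inp <- sample$input_ids; tgt <- sample$target_ids
  inp <- inp[inp != vocab$eos_id]
  tgt <- tgt[tgt != vocab$eos_id]
  is_sent_t <- tgt %in% vocab$sentinel_ids
  spans <- split(tgt[!is_sent_t], cumsum(is_sent_t)[!is_sent_t])
  sent_order <- tgt[is_sent_t]
  out <- integer(0)
  for (id in inp) {
    if (id %in% vocab$sentinel_ids) {
      key <- as.character(match(id, sent_order))
      out <- c(out, spans[[key]])
    } else {
      out <- c(out, id)
    }
  }
  out
}

#' Build teacher-forced translation samples from paired records
#'
#' AA2fold: encoder input `<AA2fold> + AA + EOS`, decoder target `3Di + EOS`;
#' fold2AA is the reverse; `both` emits one sample per direction per record.
#' Sequences are truncated to `max_len` residues before tokenization.
#'
#' @param records paired records tibble (`aa_seq`, `tdi_seq`).
#' @param direction `"AA2fold"`, `"fold2AA"` or `"both"`.
#' @param max_len truncation length in residues.
#' @param vocab a [bilingual_vocab()].
#' @return list of samples, each `list(enc_ids, dec_in_ids, dec_tgt_ids)`;
#'   decoder input is the target shifted right behind the pad start token.
#' @export
make_translation_batch <- function(records, direction = c("both", "AA2fold",
                                                          "fold2AA"),
                                   max_len = 256L, vocab = bilingual_vocab()) {
  direction <- match.arg(direction)
  if (anyNA(records$aa_seq) || anyNA(records$tdi_seq)) {
    stop("unpaired record: both aa_seq and tdi_seq are required",
         call. = FALSE)
  }
  dirs <- if (direction == "both") c("AA2fold", "fold2AA") else direction
  samples <- list()
  for (i in seq_len(nrow(records))) {
    aa <- substr(records$aa_seq[i], 1, max_len)
    tdi <- substr(records$tdi_seq[i], 1, max_len)
    for (d in dirs) {
      src <- if (d == "AA2fold") aa else tdi
      tgt <- if (d == "AA2fold") tdi else aa
      enc <- vocab_encode(vocab, src, direction = d)
      tgt_ids <- vocab_encode(vocab, tgt, direction = "none")
      samples[[length(samples) + 1L]] <-
        list(enc_ids = enc,
             dec_in_ids = c(vocab$pad_id, tgt_ids[-length(tgt_ids)]),
             dec_tgt_ids = tgt_ids,
             direction = d)
    }
  }
  samples
}

# Denoising samples for one modality.
make_denoise_batch <- function(records, modality, max_len, vocab, rate,
                               mean_span) {
  col <- if (modality == "AA") "aa_seq" else "tdi_seq"
  lapply(records[[col]], function(s) {
    s <- substr(s, 1, max_len)
    ids <- vocab_encode(vocab, s, direction = "none", add_eos = FALSE)
    cs <- span_corrupt(ids, vocab, rate, mean_span)
    list(enc_ids = cs$input_ids,
         dec_in_ids = c(vocab$pad_id,
                        cs$target_ids[-length(cs$target_ids)]),
         dec_tgt_ids = cs$target_ids)
  })
}

run_batch <- function(model, samples, want_grads = TRUE) {
  seq2seq_loss(model$params, model$dims,
               lapply(samples, `[[`, "enc_ids"),
               lapply(samples, `[[`, "dec_in_ids"),
               lapply(samples, `[[`, "dec_tgt_ids"),
               want_grads = want_grads)
}

#' Evaluate teacher-forced loss and token accuracy on records
#'
#' @param model a `fold_model`.
#' @param records paired records.
#' @param direction `"AA2fold"` or `"fold2AA"`.
#' @param max_records subsample cap (0 = all).
#' @return list with `loss` and `accuracy` (per-token, teacher forced).
#' @export
teacher_forced_eval <- function(model, records,
                                direction = c("AA2fold", "fold2AA"),
                                max_records = 0L) {
  direction <- match.arg(direction)
  if (max_records > 0 && nrow(records) > max_records) {
    records <- records[seq_len(max_records), ]
  }
  out <- list(loss = numeric(0), acc = numeric(0), n = numeric(0))
  chunk <- 16L
  for (s in seq(1, nrow(records), by = chunk)) {
    recs <- records[s:min(nrow(records), s + chunk - 1L), ]
    batch <- make_translation_batch(recs, direction, 10000L, model$vocab)
    r <- run_batch(model, batch, want_grads = FALSE)
    out$loss <- c(out$loss, r$loss); out$acc <- c(out$acc, r$accuracy)
    out$n <- c(out$n, r$n_tok)
  }
  list(loss = sum(out$loss * out$n) / sum(out$n),
       accuracy = sum(out$acc * out$n) / sum(out$n))
}

#' Train the bilingual translation model
#'
#' Phase 1 minimizes span-denoising cross-entropy with batches alternating
#' between the AA and 3Di modalities; phase 2 minimizes translation
#' cross-entropy with batches alternating between the two directions, under
#' the max-length curriculum. Validation losses (per modality in phase 1, per
#' direction in phase 2) are recorded at the configured cadence.
#'
#' @param records curated records with a `split` column (`train` / `val`).
#' @param cfg a [train_config()].
#' @param vocab a [bilingual_vocab()].
#' @param checkpoint_dir if non-`NULL`, the final weights (RDS), vocabulary
#'   JSON, config snapshot (YAML) and loss trace (TSV) are written there.
#' @param quiet suppress progress log lines.
#' @return a `fold_model`: `params`, `dims`, `vocab`, `trace` (tibble of
#'   training and validation losses), `cfg`.
#' @export
train_translation_model <- function(records, cfg = train_config(),
                                    vocab = bilingual_vocab(16),
                                    checkpoint_dir = NULL, quiet = FALSE) {
  train <- records[records$split == "train", ]
  val <- records[records$split == "val", ]
  if (nrow(train) == 0) stop("empty training split", call. = FALSE)
  if (nrow(val) == 0) stop("empty validation split", call. = FALSE)
  dims <- list(n_layers = cfg$model_dims[1], d = cfg$model_dims[2],
               n_heads = cfg$model_dims[3])
  params <- init_params(vocab_size(vocab), dims$d, dims$n_layers,
                        dims$n_heads, seed = cfg$seed)
  model <- structure(list(params = params, dims = dims, vocab = vocab,
                          trace = NULL, cfg = cfg), class = "fold_model")
  opt <- adam_init(params)
  trace <- list()
  push <- function(phase, step, kind, value) {
    trace[[length(trace) + 1L]] <<- tibble::tibble(
      phase = phase, step = step, metric = kind, value = value)
  }
  val_cap <- cfg$val_max_records

  withr::with_seed(cfg$seed + 1L, {
    # ---- phase 1: span denoising, alternating modalities ----
    for (step in seq_len(cfg$steps)) {
      modality <- if (step %% 2 == 1) "AA" else "3Di"
      grads_sum <- NULL; loss_acc <- 0
      for (a in seq_len(cfg$grad_accum)) {
        idx <- sample.int(nrow(train), min(cfg$batch_size, nrow(train)))
        batch <- make_denoise_batch(train[idx, ], modality,
                                    cfg$phase1_max_len, vocab,
                                    cfg$corruption_rate, cfg$mean_span_len)
        r <- run_batch(model, batch)
        loss_acc <- loss_acc + r$loss / cfg$grad_accum
        grads_sum <- accumulate_grads(grads_sum, r$grads, 1 / cfg$grad_accum)
      }
      st <- adam_step(model$params, grads_sum, opt, cfg$phase1_lr)
      model$params <- st$p; opt <- st$opt
      push("denoise", step, paste0("train_loss_", modality), loss_acc)
      if (cfg$val_every > 0 && step %% cfg$val_every == 0) {
        for (mo in c("AA", "3Di")) {
          vb <- make_denoise_batch(utils::head(val, val_cap), mo,
                                   cfg$phase1_max_len, vocab,
                                   cfg$corruption_rate, cfg$mean_span_len)
          push("denoise", step, paste0("val_loss_", mo),
               run_batch(model, vb, want_grads = FALSE)$loss)
        }
        if (!quiet) flog("phase1 step %d/%d loss %.3f", step, cfg$steps,
                         loss_acc)
      }
    }
    # ---- phase 2: bidirectional translation with length curriculum ----
    step2 <- 0L
    for (seg in cfg$phase2_max_len_schedule) {
      seg_steps <- seg[1]; max_len <- seg[2]
      for (s in seq_len(seg_steps)) {
        step2 <- step2 + 1L
        dir <- if (step2 %% 2 == 1) "AA2fold" else "fold2AA"
        grads_sum <- NULL; loss_acc <- 0
        for (a in seq_len(cfg$grad_accum)) {
          idx <- sample.int(nrow(train), min(cfg$batch_size, nrow(train)))
          batch <- make_translation_batch(train[idx, ], dir, max_len, vocab)
          r <- run_batch(model, batch)
          loss_acc <- loss_acc + r$loss / cfg$grad_accum
          grads_sum <- accumulate_grads(grads_sum, r$grads, 1 / cfg$grad_accum)
        }
        st <- adam_step(model$params, grads_sum, opt, cfg$phase2_lr)
        model$params <- st$p; opt <- st$opt
        push("translate", step2, paste0("train_loss_", dir), loss_acc)
        if (cfg$val_every > 0 && step2 %% cfg$val_every == 0) {
          for (d in c("AA2fold", "fold2AA")) {
            ev <- teacher_forced_eval(model, val, d, max_records = val_cap)
            push("translate", step2, paste0("val_loss_", d), ev$loss)
            push("translate", step2, paste0("val_acc_", d), ev$accuracy)
          }
          if (!quiet) flog("phase2 step %d loss %.3f", step2, loss_acc)
        }
      }
    }
  })
  model$trace <- dplyr::bind_rows(trace)
  if (!is.null(checkpoint_dir)) save_model(model, checkpoint_dir)
  model
}

accumulate_grads <- function(acc, grads, weight) {
  if (is.null(acc)) {
    acc <- new.env(parent = emptyenv())
    for (nm in ls(grads)) acc[[nm]] <- grads[[nm]] * weight
  } else {
    for (nm in ls(grads)) acc[[nm]] <- acc[[nm]] + grads[[nm]] * weight
  }
  acc
}

#' @export
print.fold_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<fold_model> %d layers, width %d, %d heads | %s parameters | vocab %d\n",
              x$dims$n_layers, x$dims$d, x$dims$n_heads,
              format(n_par, big.mark = ","), vocab_size(x$vocab)))
  invisible(x)
}

#' Save / load a trained model checkpoint directory
#'
#' Weights as RDS, vocabulary as JSON, dimensions as YAML, loss trace as TSV.
#' @param model a `fold_model`.
#' @param dir checkpoint directory (created if missing).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  write_vocab_json(model$vocab, file.path(dir, "vocab.json"))
  yaml::write_yaml(list(n_layers = model$dims$n_layers, d = model$dims$d,
                        n_heads = model$dims$n_heads),
                   file.path(dir, "dims.yaml"))
  if (!is.null(model$trace)) {
    readr::write_tsv(model$trace, file.path(dir, "loss_trace.tsv"))
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  dims <- yaml::read_yaml(file.path(dir, "dims.yaml"))
  trace_path <- file.path(dir, "loss_trace.tsv")
  structure(list(
    params = readRDS(file.path(dir, "weights.rds")),
    dims = dims,
    vocab = read_vocab_json(file.path(dir, "vocab.json")),
    trace = if (file.exists(trace_path))
      readr::read_tsv(trace_path, show_col_types = FALSE) else NULL,
    cfg = NULL), class = "fold_model")
}

#' Per-residue encoder embeddings for one sequence
#'
#' Runs the encoder with the translation-direction prefix and returns the
#' hidden states of its last layer for the residue positions (prefix and
#' end-of-sequence rows dropped): one row per residue, `width` columns.
#'
#' @param model a `fold_model`.
#' @param seq amino-acid or 3Di string.
#' @param direction prefix to use; default inferred from the sequence casing
#'   (`AA2fold` for AA input, `fold2AA` for 3Di input).
#' @return `nchar(seq) x width` numeric matrix.
#' @export
encoder_embed <- function(model, seq, direction = NULL) {
  if (is.null(direction)) {
    direction <- if (infer_alphabet(seq) == "AA") "AA2fold" else "fold2AA"
  }
  ids <- vocab_encode(model$vocab, seq, direction = direction)
  H <- encode_hidden(model$params, model$dims, ids)
  H[2:(nrow(H) - 1L), , drop = FALSE]
}

#' Mean-pool a per-residue embedding matrix to one protein vector
#' @param embedding `L x width` matrix from [encoder_embed()].
#' @return numeric vector of length `width`.
#' @export
mean_pool <- function(embedding) colMeans(embedding)
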