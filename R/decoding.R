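# Autoregressive generation: the logit-processing stack (repetition penalty,
# temperature, top-k, nucleus, alphabet constraint) and ancestral /
# stochastic-beam decoding.
#
# Processor order is fixed as penalty -> temperature -> top-k -> top-p ->
# constraint -> softmax, the convention of the generation framework the
# published configuration keys come from; reordering changes distributions.

#' Decoding configuration
#'
#' @param do_sample sample from the processed distribution (`TRUE`) or decode
#'   greedily (`FALSE`).
#' @param num_beams number of translation paths explored in parallel (>= 1).
#' @param temperature logit divisor before softmax (> 0); higher increases
#'   randomness.
#' @param top_p nucleus threshold in `(0, 1]`: keep the smallest
#'   probability-sorted prefix whose cumulative probability reaches `top_p`.
#' @param top_k keep only the `top_k` most probable tokens (0 = off).
#' @param repetition_penalty penalty (>= 1) applied to tokens already
#'   generated: positive logits are divided by it, negative logits
#'   multiplied.
#' @param max_new_tokens generation budget.
#' @param seed integer seed for reproducible sampling (`NULL` = use the
#'   current RNG state).
#' @param constrain_alphabet restrict generation to the target alphabet
#'   (plus end-of-sequence).
#' @return a `decode_config` list.
#' @export
decode_config <- function(do_sample = FALSE, num_beams = 1L, temperature = 1,
                          top_p = 1, top_k = 0L, repetition_penalty = 1,
                          max_new_tokens = 128L, seed = NULL,
                          constrain_alphabet = TRUE) {
  stopifnot(num_beams >= 1, temperature > 0, top_p > 0, top_p <= 1,
            top_k >= 0, repetition_penalty >= 1, max_new_tokens >= 1)
  structure(list(do_sample = do_sample, num_beams = as.integer(num_beams),
                 temperature = temperature, top_p = top_p,
                 top_k = as.integer(top_k),
                 repetition_penalty = repetition_penalty,
                 max_new_tokens = as.integer(max_new_tokens),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 constrain_alphabet = constrain_alphabet),
            class = "decode_config")
}

#' Published generation configuration for AA -> 3Di (folding)
#' @param ... overrides passed to [decode_config()].
#' @export
decode_config_folding <- function(...) {
  args <- utils::modifyList(
    list(do_sample = TRUE, num_beams = 3L, temperature = 1.2, top_p = 0.95,
         top_k = 6L, repetition_penalty = 1.2), list(...))
  do.call(decode_config, args)
}

#' Published generation configuration for 3Di -> AA (inverse folding)
#' @param ... overrides passed to [decode_config()].
#' @export
decode_config_inverse_folding <- function(...) {
  args <- utils::modifyList(
    list(do_sample = TRUE, num_beams = 1L, temperature = 1.0, top_p = 0.85,
         top_k = 3L, repetition_penalty = 1.2), list(...))
  do.call(decode_config, args)
}

#' Process next-token logits into a sampling distribution
#'
#' Applies, in order: (1) repetition penalty over tokens already generated
#' (positive logits divided, negative logits multiplied by the penalty);
#' (2) temperature division; (3) top-k truncation; (4) nucleus (top-p)
#' truncation keeping the minimal probability-sorted prefix reaching `top_p`
#' (boundary token included); (5) an optional allowed-token mask;
#' (6) softmax renormalization.
#'
#' @param logits finite numeric vector over the vocabulary.
#' @param generated integer ids (1-based positions into `logits`) already
#'   generated.
#' @param cfg a [decode_config()].
#' @param allowed optional integer vector of permitted positions (the
#'   alphabet constraint); `NULL` = all.
#' @return probability vector summing to 1 (masked entries exactly 0).
#' @export
process_logits <- function(logits, generated, cfg, allowed = NULL) {
  if (any(!is.finite(logits))) stop("logits must be finite", call. = FALSE)
  z <- logits
  rep_ids <- unique(generated)
  if (cfg$repetition_penalty != 1 && length(rep_ids) > 0) {
    pos <- z[rep_ids] > 0
    z[rep_ids[pos]] <- z[rep_ids[pos]] / cfg$repetition_penalty
    z[rep_ids[!pos]] <- z[rep_ids[!pos]] * cfg$repetition_penalty
  }
  z <- z / cfg$temperature
  keep <- rep(TRUE, length(z))
  if (cfg$top_k > 0 && cfg$top_k < length(z)) {
    thresh <- sort(z, decreasing = TRUE)[cfg$top_k]
    drop <- z < thresh
    # ties at the threshold: keep lowest indices first, up to k tokens
    at <- which(z == thresh & !drop)
    n_keep_above <- sum(z > thresh)
    if (n_keep_above + length(at) > cfg$top_k) {
      drop[at[-(seq_len(cfg$top_k - n_keep_above))]] <- TRUE
    }
    keep <- keep & !drop
  }
  if (cfg$top_p < 1) {
    zk <- z; zk[!keep] <- -Inf
    pk <- exp(zk - max(zk)); pk <- pk / sum(pk)
    ord <- order(pk, decreasing = TRUE)
    cum <- cumsum(pk[ord])
    n_nucleus <- which(cum >= cfg$top_p - 1e-12)[1]
    keep <- keep & seq_along(z) %in% ord[seq_len(n_nucleus)]
  }
  if (!is.null(allowed)) keep <- keep & seq_along(z) %in% allowed
  if (!any(keep)) stop("all tokens masked by the logit processors",
                       call. = FALSE)
  z[!keep] <- -Inf
  p <- exp(z - max(z))
  p / sum(p)
}

#' Translate a sequence with the trained model
#'
#' `num_beams = 1`: ancestral sampling (or greedy argmax when
#' `do_sample = FALSE`) through [process_logits()] until end-of-sequence or
#' the token budget. `num_beams > 1` with `do_sample = TRUE`: stochastic beam
#' search — every live beam extends by sampling from its processed
#' distribution, beams are ranked by length-normalized log-probability and
#' the best finished beam is returned; with `do_sample = FALSE` extensions
#' are the top-probability continuations. Deterministic given `cfg$seed`.
#'
#' @param model a `fold_model`.
#' @param seq source sequence (alphabet implied by `direction`).
#' @param direction `"AA2fold"` (AA in, 3Di out) or `"fold2AA"`.
#' @param cfg a [decode_config()].
#' @return generated string in the target alphabet.
#' @export
translate <- function(model, seq, direction = c("AA2fold", "fold2AA"),
                      cfg = decode_config()) {
  direction <- match.arg(direction)
  vocab <- model$vocab
  enc_ids <- vocab_encode(vocab, seq, direction = direction)
  enc_H <- encode_hidden(model$params, model$dims, enc_ids)
  target_ids <- if (direction == "AA2fold") vocab$tdi_ids else vocab$aa_ids
  allowed <- if (cfg$constrain_alphabet) {
    c(target_ids, vocab$eos_id) + 1L
  } else NULL
  # The alphabet constraint acts as a logits processor ahead of the
  # truncation warpers (the convention of the framework the published
  # configs come from): clamp disallowed logits before top-k/top-p so the
  # truncated candidate set is never empty. process_logits additionally
  # masks as its own step, which keeps the contract for direct callers.
  clamp <- function(logits) {
    if (!is.null(allowed)) {
      logits[-allowed] <- min(logits[allowed]) - 1e4
    }
    logits
  }

  run <- function() {
    n_beams <- cfg$num_beams
    beams <- replicate(n_beams, list(ids = vocab$pad_id, out = integer(0),
                                     logp = 0, done = FALSE),
                       simplify = FALSE)
    if (n_beams == 1) {
      b <- beams[[1]]
      for (step in seq_len(cfg$max_new_tokens)) {
        logits <- clamp(decoder_last_logits(model$params, model$dims, b$ids,
                                            enc_H))
        p <- process_logits(logits, b$out + 1L, cfg, allowed)
        nxt <- if (cfg$do_sample) {
          sample.int(length(p), 1, prob = p)
        } else which.max(p)
        if (nxt - 1L == vocab$eos_id) break
        b$ids <- c(b$ids, nxt - 1L)
        b$out <- c(b$out, nxt - 1L)
      }
      return(vocab_decode(vocab, b$out))
    }
    for (step in seq_len(cfg$max_new_tokens)) {
      if (all(vapply(beams, `[[`, logical(1), "done"))) break
      for (bi in seq_len(n_beams)) {
        b <- beams[[bi]]
        if (b$done) next
        logits <- clamp(decoder_last_logits(model$params, model$dims, b$ids,
                                            enc_H))
        p <- process_logits(logits, b$out + 1L, cfg, allowed)
        nxt <- if (cfg$do_sample) {
          sample.int(length(p), 1, prob = p)
        } else which.max(p)
        b$logp <- b$logp + log(p[nxt])
        if (nxt - 1L == vocab$eos_id) {
          b$done <- TRUE
        } else {
          b$ids <- c(b$ids, nxt - 1L)
          b$out <- c(b$out, nxt - 1L)
        }
        beams[[bi]] <- b
      }
    }
    # length-normalized log-probability; ties broken by beam index
    scores <- vapply(beams, function(b) b$logp / max(1, length(b$out) + 1),
                     numeric(1))
    finished <- vapply(beams, `[[`, logical(1), "done")
    cand <- if (any(finished)) which(finished) else seq_len(n_beams)
    best <- cand[which.max(scores[cand])]
    vocab_decode(vocab, beams[[best]]$out)
  }
  if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, run()) else run()
}
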