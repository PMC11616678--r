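# The bilingual vocabulary: amino-acid tokens (upper case), 3Di tokens (lower
# case), translation-direction prefixes, span-corruption sentinels and the
# pad / end-of-sequence / unknown specials. Token ids are assigned
# contiguously, 0-based, and the AA and 3Di id ranges never overlap.

PAD_TOKEN <- "<pad>"
EOS_TOKEN <- "</s>"
UNK_TOKEN <- "<unk>"
AA2FOLD_TOKEN <- "<AA2fold>"
FOLD2AA_TOKEN <- "<fold2AA>"

#' Construct the bilingual token vocabulary
#'
#' Ids are 0-based: pad 0, end-of-sequence 1, unknown 2, then the 20 amino
#' acids, the 20 3Di letters, the two direction prefixes and `n_sentinel`
#' span-corruption sentinels.
#'
#' @param n_sentinel number of sentinel tokens (default 128; toy models may
#'   use fewer).
#' @return a `bilingual_vocab` object.
#' @examples
#' v <- bilingual_vocab(16)
#' vocab_decode(v, vocab_encode(v, "ACDY", direction = "AA2fold"))
#' @export
bilingual_vocab <- function(n_sentinel = 128) {
  stopifnot(n_sentinel >= 1)
  sentinels <- sprintf("<extra_id_%d>", seq_len(n_sentinel) - 1)
  tokens <- c(PAD_TOKEN, EOS_TOKEN, UNK_TOKEN,
              AA_LETTERS, c("X"),
              TDI_LETTERS,
              AA2FOLD_TOKEN, FOLD2AA_TOKEN,
              sentinels)
  stopifnot(!anyDuplicated(tokens))
  ids <- seq_along(tokens) - 1L
  token_to_id <- stats::setNames(ids, tokens)
  v <- structure(list(
    tokens = tokens,
    token_to_id = token_to_id,
    n_sentinel = n_sentinel,
    aa_ids = unname(token_to_id[c(AA_LETTERS, "X")]),
    tdi_ids = unname(token_to_id[TDI_LETTERS]),
    prefix_ids = unname(token_to_id[c(AA2FOLD_TOKEN, FOLD2AA_TOKEN)]),
    sentinel_ids = unname(token_to_id[sentinels]),
    pad_id = 0L, eos_id = 1L, unk_id = 2L
  ), class = "bilingual_vocab")
  stopifnot(length(intersect(v$aa_ids, v$tdi_ids)) == 0)
  v
}

#' @export
print.bilingual_vocab <- function(x, ...) {
  cat(sprintf("<bilingual_vocab> %d tokens (20 AA + X, 20 3Di, 2 prefixes, %d sentinels, 3 specials)\n",
              length(x$tokens), x$n_sentinel))
  invisible(x)
}

vocab_size <- function(vocab) length(vocab$tokens)

#' Encode a sequence into token ids
#'
#' Output is `[direction prefix?] + one id per character + end-of-sequence`.
#' With `direction = "none"` the alphabet is inferred from casing and no
#' prefix is added.
#'
#' @param vocab a [bilingual_vocab()].
#' @param seq amino-acid (upper) or 3Di (lower) string.
#' @param direction `"AA2fold"`, `"fold2AA"` or `"none"`.
#' @param add_eos append the end-of-sequence id (default TRUE).
#' @return integer vector of 0-based token ids.
#' @export
vocab_encode <- function(vocab, seq, direction = c("none", "AA2fold", "fold2AA"),
                         add_eos = TRUE) {
  direction <- match.arg(direction)
  alphabet <- switch(direction,
    AA2fold = "AA", fold2AA = "3Di", none = infer_alphabet(seq))
  if (grepl("[A-Z]", seq) && grepl("[a-z]", seq)) {
    stop("mixed-case sequence cannot be encoded", call. = FALSE)
  }
  validate_seq(seq, alphabet, id = "<encode>")
  chars <- split_chars(seq)
  ids <- vocab$token_to_id[chars]
  if (anyNA(ids)) {
    stop("character not in vocabulary: ", chars[which(is.na(ids))[1]],
         call. = FALSE)
  }
  prefix <- switch(direction,
    AA2fold = vocab$token_to_id[[AA2FOLD_TOKEN]],
    fold2AA = vocab$token_to_id[[FOLD2AA_TOKEN]],
    none = integer(0))
  out <- c(prefix, unname(ids))
  if (add_eos) out <- c(out, vocab$eos_id)
  as.integer(out)
}

#' Decode token ids back to a residue string
#'
#' Prefixes, sentinels, pad and end-of-sequence ids are stripped; residue
#' tokens are concatenated in order.
#'
#' @param vocab a [bilingual_vocab()].
#' @param ids integer vector of 0-based token ids.
#' @return string.
#' @export
vocab_decode <- function(vocab, ids) {
  ids <- as.integer(ids)
  if (any(ids < 0 | ids >= vocab_size(vocab))) {
    stop("unknown token id: ", ids[which(ids < 0 | ids >= vocab_size(vocab))[1]],
         call. = FALSE)
  }
  drop <- c(vocab$pad_id, vocab$eos_id, vocab$prefix_ids, vocab$sentinel_ids)
  keep <- ids[!ids %in% drop]
  paste(vocab$tokens[keep + 1L], collapse = "")
}

#' Serialize / restore a vocabulary as a JSON token-to-id map
#' @param vocab a [bilingual_vocab()].
#' @param path JSON file.
#' @export
write_vocab_json <- function(vocab, path) {
  jsonlite::write_json(as.list(vocab$token_to_id), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocab_json
#' @export
read_vocab_json <- function(path) {
  m <- unlist(jsonlite::read_json(path))
  n_sent <- sum(startsWith(names(m), "<extra_id_"))
  v <- bilingual_vocab(n_sentinel = n_sent)
  if (!identical(stats::setNames(as.integer(m), names(m)),
                 stats::setNames(as.integer(v$token_to_id), names(v$token_to_id)))) {
    stop("vocabulary JSON does not match the canonical id assignment",
         call. = FALSE)
  }
  v
}
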