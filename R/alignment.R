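# Global alignment under a custom substitution matrix with affine gaps,
# sequence-level generation metrics (PIDE, similarity, KL naturalness) and
# the roundtrip-accuracy filter for inverse folding.
#
# Gap convention: a gap run of length k scores gap_open + k * gap_extend.

#' Construct a substitution matrix object
#'
#' @param alphabet character vector of unique lower-case letters.
#' @param scores square symmetric integer matrix in alphabet order.
#' @param gap_open,gap_extend gap penalties (<= 0); a run of k gap columns
#'   scores `gap_open + k * gap_extend`.
#' @param strict require the 20-letter 3Di alphabet size.
#' @return a `subst_matrix` object.
#' @export
subst_matrix <- function(alphabet, scores, gap_open = -10L, gap_extend = -1L,
                         strict = TRUE) {
  alphabet <- tolower(alphabet)
  n <- length(alphabet)
  if (anyDuplicated(alphabet)) stop("alphabet letters must be unique",
                                    call. = FALSE)
  if (strict && n != 20) {
    stop(sprintf("expected a 20-letter alphabet, got %d", n), call. = FALSE)
  }
  if (!is.matrix(scores) || nrow(scores) != n || ncol(scores) != n) {
    stop("scores must be a square matrix matching the alphabet",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(scores, t(scores)))) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  if (gap_open > 0 || gap_extend > 0) {
    stop("gap penalties must be <= 0", call. = FALSE)
  }
  dimnames(scores) <- list(alphabet, alphabet)
  structure(list(alphabet = alphabet, scores = scores,
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend)),
            class = "subst_matrix")
}

#' @export
print.subst_matrix <- function(x, ...) {
  cat(sprintf("<subst_matrix> %d letters, gap open %g / extend %g\n",
              length(x$alphabet), x$gap_open, x$gap_extend))
  invisible(x)
}

#' A synthetic 3Di substitution matrix
#'
#' Stand-in for a structure-alignment substitution matrix, built from the
#' synthetic alphabet's design rather than from real structural data:
#' identities score +6, substitutions between tokens preferring the same
#' secondary-structure class +1, all others -3. Also shipped as
#' `inst/extdata/substmat_3di_synthetic.mat`.
#'
#' @param gap_open,gap_extend gap penalties.
#' @return a `subst_matrix` over the 20 3Di letters.
#' @export
synthetic_3di_matrix <- function(gap_open = -10L, gap_extend = -1L) {
  pref <- TDI_SS3_PREF[TDI_LETTERS]
  scores <- matrix(-3L, 20, 20)
  same <- outer(pref, pref, "==")
  scores[same] <- 1L
  diag(scores) <- 6L
  subst_matrix(TDI_LETTERS, scores, gap_open, gap_extend)
}

#' Global Needleman-Wunsch alignment with affine gaps
#'
#' Optimal global alignment of two strings under a custom substitution matrix
#' and affine gap penalties, with deterministic traceback (ties broken
#' diagonal, then up, then left).
#'
#' @param a,b strings over `mat$alphabet`.
#' @param mat a [subst_matrix()].
#' @param pide_denominator `"alignment"` (default: alignment length including
#'   gap columns) or `"shorter"` (length of the shorter sequence).
#' @return an `alignment_result`: `aligned_a`, `aligned_b` (gapped, equal
#'   length), `score`, `pide` and `similarity` (both percentages),
#'   `identities`, `alignment_length`.
#' @examples
#' m <- synthetic_3di_matrix()
#' nw_align("vvdpa", "vvda", m)$pide
#' @export
nw_align <- function(a, b, mat, pide_denominator = c("alignment", "shorter")) {
  pide_denominator <- match.arg(pide_denominator)
  ai <- match(split_chars(a), mat$alphabet)
  bi <- match(split_chars(b), mat$alphabet)
  if (anyNA(ai)) stop("sequence a has a character outside the matrix alphabet",
                      call. = FALSE)
  if (anyNA(bi)) stop("sequence b has a character outside the matrix alphabet",
                      call. = FALSE)
  n <- length(ai); m <- length(bi)
  go <- mat$gap_open; ge <- mat$gap_extend
  NEG <- -Inf
  # state matrices: M diagonal, X gap in b (consumes a, "up"), Y gap in a
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  if (n > 0) X[2:(n + 1), 1] <- go + ge * seq_len(n)
  if (m > 0) Y[1, 2:(m + 1)] <- go + ge * seq_len(m)
  S <- mat$scores
  for (i in seq_len(n)) {
    srow <- S[ai[i], ]
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + srow[bi[j]]
      X[i + 1, j + 1] <- max(M[i, j + 1] + go + ge, X[i, j + 1] + ge,
                             Y[i, j + 1] + go + ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + go + ge, X[i + 1, j] + go + ge,
                             Y[i + 1, j] + ge)
    }
  }
  # traceback; state priority M > X > Y realizes diagonal > up > left
  pick <- function(vals) which.max(vals + c(2e-9, 1e-9, 0))
  i <- n; j <- m
  final <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- pick(final)
  score <- final[state]
  ga <- character(0); gb <- character(0)
  while (i > 0 || j > 0) {
    if (state == 1) {
      ga <- c(mat$alphabet[ai[i]], ga); gb <- c(mat$alphabet[bi[j]], gb)
      prev <- pick(c(M[i, j], X[i, j], Y[i, j]))
      i <- i - 1; j <- j - 1; state <- prev
    } else if (state == 2) {
      ga <- c(mat$alphabet[ai[i]], ga); gb <- c("-", gb)
      prev <- pick(c(M[i, j + 1] + go + ge, X[i, j + 1] + ge,
                     Y[i, j + 1] + go + ge) - X[i + 1, j + 1])
      i <- i - 1; state <- prev
    } else {
      ga <- c("-", ga); gb <- c(mat$alphabet[bi[j]], gb)
      prev <- pick(c(M[i + 1, j] + go + ge, X[i + 1, j] + go + ge,
                     Y[i + 1, j] + ge) - Y[i + 1, j + 1])
      j <- j - 1; state <- prev
    }
  }
  len <- length(ga)
  ident <- sum(ga == gb & ga != "-")
  pos <- sum(ga != "-" & gb != "-" &
               mat$scores[cbind(match(ga, mat$alphabet),
                                match(gb, mat$alphabet))] > 0, na.rm = TRUE)
  denom <- if (pide_denominator == "alignment") len else max(1, min(n, m))
  structure(list(
    aligned_a = paste(ga, collapse = ""),
    aligned_b = paste(gb, collapse = ""),
    score = score,
    pide = if (len == 0) 0 else 100 * ident / denom,
    similarity = if (len == 0) 0 else 100 * pos / denom,
    identities = ident, alignment_length = len
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score %g | PIDE %.1f%% | similarity %.1f%%\n",
              x$score, x$pide, x$similarity))
  invisible(x)
}

#' Kullback-Leibler naturalness of generated amino-acid sequences
#'
#' KL divergence (nats) of the pooled empirical amino-acid distribution of
#' the generated sequences from a reference composition; 0 iff identical.
#'
#' @param generated character vector of AA sequences.
#' @param reference_freqs strictly positive named 20-vector summing to 1 (in
#'   `AA_LETTERS` order if unnamed).
#' @return non-negative scalar.
#' @export
kl_naturalness <- function(generated, reference_freqs) {
  if (length(generated) == 0 || all(nchar(generated) == 0)) {
    stop("no generated sequences", call. = FALSE)
  }
  if (is.null(names(reference_freqs))) names(reference_freqs) <- AA_LETTERS
  q <- reference_freqs[AA_LETTERS]
  if (any(is.na(q)) || any(q <= 0) || abs(sum(q) - 1) > 1e-6) {
    stop("reference_freqs must be strictly positive over the 20 amino acids and sum to 1",
         call. = FALSE)
  }
  chars <- unlist(strsplit(paste(generated, collapse = ""), ""))
  counts <- table(factor(chars, levels = AA_LETTERS))
  p <- as.numeric(counts) / sum(counts)
  sum(ifelse(p > 0, p * log(p / as.numeric(q)), 0))
}

#' Roundtrip accuracy of a generated amino-acid sequence
#'
#' Translates the generated AA sequence back to 3Di with the model and
#' returns the PIDE (on the 3Di substitution matrix) between that
#' back-translation and the native 3Di string: the 3Di -> AA -> 3Di
#' self-consistency score.
#'
#' @param native_tdi native 3Di string.
#' @param generated_aa generated amino-acid sequence.
#' @param model a trained [train_translation_model()] model.
#' @param cfg a [decode_config()] for the AA -> 3Di back-translation.
#' @param mat a [subst_matrix()] over the 3Di alphabet.
#' @return PIDE in `[0, 100]`.
#' @export
roundtrip_accuracy <- function(native_tdi, generated_aa, model, cfg, mat) {
  back <- translate(model, generated_aa, direction = "AA2fold", cfg = cfg)
  nw_align(native_tdi, back, mat)$pide
}

#' Inverse folding with the roundtrip filter
#'
#' Samples amino-acid candidates from the 3Di -> AA direction, scores each by
#' its roundtrip accuracy, stops as soon as a candidate reaches `threshold`
#' (never exceeding `budget` attempts) and retains the candidate with the
#' maximal roundtrip accuracy.
#'
#' @param native_tdi native 3Di string.
#' @param model trained model.
#' @param cfg_fwd [decode_config()] for the AA -> 3Di back-translation.
#' @param cfg_back [decode_config()] for the 3Di -> AA generation.
#' @param mat 3Di [subst_matrix()].
#' @param threshold acceptance threshold on roundtrip PIDE (default 70).
#' @param budget maximum attempts (default 10).
#' @return a `roundtrip_result`: `candidates` tibble (`aa_seq`,
#'   `roundtrip_pide`), `accepted` (AA string or `NA` if no candidate met the
#'   threshold; the best candidate is still recorded), `n_attempts`.
#' @export
generate_with_roundtrip <- function(native_tdi, model, cfg_fwd, cfg_back,
                                    mat, threshold = 70, budget = 10) {
  if (budget < 1) stop("budget must be >= 1", call. = FALSE)
  aa <- character(0); sc <- numeric(0)
  for (attempt in seq_len(budget)) {
    cfg_b <- cfg_back; cfg_f <- cfg_fwd
    if (!is.null(cfg_b$seed)) cfg_b$seed <- cfg_b$seed + attempt - 1L
    if (!is.null(cfg_f$seed)) cfg_f$seed <- cfg_f$seed + attempt - 1L
    cand <- translate(model, native_tdi, direction = "fold2AA", cfg = cfg_b)
    aa[attempt] <- cand
    sc[attempt] <- if (nchar(cand) == 0) 0 else
      roundtrip_accuracy(native_tdi, cand, model, cfg_f, mat)
    if (sc[attempt] >= threshold) break
  }
  best <- which.max(sc)
  structure(list(
    candidates = tibble::tibble(aa_seq = aa, roundtrip_pide = sc),
    accepted = if (sc[best] >= threshold) aa[best] else NA_character_,
    n_attempts = length(sc)
  ), class = "roundtrip_result")
}

#' @export
print.roundtrip_result <- function(x, ...) {
  cat(sprintf("<roundtrip_result> %d attempt(s), best roundtrip %.1f%%, %s\n",
              x$n_attempts, max(x$candidates$roundtrip_pide),
              if (is.na(x$accepted)) "no candidate accepted" else "accepted"))
  invisible(x)
}
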