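# The fast inference path: a two-layer 1-D convolutional classifier over
# frozen encoder embeddings, predicting the 20 3Di states per residue, with
# confidence thresholding for the precision/coverage trade-off.

#' Configuration of the convolutional 3Di classification head
#'
#' @param kernel_size odd convolution width (symmetric zero padding keeps the
#'   output length equal to the input length).
#' @param hidden_channels channels of the intermediate layer.
#' @param dropout input dropout rate during training.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size proteins per optimizer step.
#' @param seed seed for init, shuffling and dropout.
#' @return a `head_config` list.
#' @export
head_config <- function(kernel_size = 7L, hidden_channels = 32L, dropout = 0,
                        epochs = 6L, lr = 1e-3, batch_size = 16L, seed = 1L) {
  stopifnot(kernel_size %% 2 == 1, kernel_size >= 1, hidden_channels >= 1,
            dropout >= 0, dropout < 1, epochs >= 1, lr > 0, batch_size >= 1)
  structure(list(kernel_size = as.integer(kernel_size),
                 hidden_channels = as.integer(hidden_channels),
                 dropout = dropout, epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "head_config")
}

# L x d -> L x (k*d): row i holds the zero-padded window centered at i.
unfold_rows <- function(X, k) {
  L <- nrow(X); d <- ncol(X); half <- (k - 1L) %/% 2L
  U <- matrix(0, L, k * d)
  for (o in seq_len(k)) {
    shift <- o - 1L - half
    src <- seq_len(L) + shift
    ok <- src >= 1L & src <= L
    U[ok, ((o - 1L) * d + 1L):(o * d)] <- X[src[ok], , drop = FALSE]
  }
  U
}

# Adjoint of unfold_rows: scatter dU back onto dX.
fold_rows <- function(dU, k, d) {
  L <- nrow(dU); half <- (k - 1L) %/% 2L
  dX <- matrix(0, L, d)
  for (o in seq_len(k)) {
    shift <- o - 1L - half
    src <- seq_len(L) + shift
    ok <- src >= 1L & src <= L
    dX[src[ok], ] <- dX[src[ok], ] +
      dU[ok, ((o - 1L) * d + 1L):(o * d), drop = FALSE]
  }
  dX
}

head_forward <- function(hp, X, k) {
  U1 <- unfold_rows(X, k)
  H <- pmax(sweep(U1 %*% hp$W1, 2, hp$b1, "+"), 0)
  U2 <- unfold_rows(H, k)
  logits <- sweep(U2 %*% hp$W2, 2, hp$b2, "+")
  list(U1 = U1, H = H, U2 = U2, logits = logits)
}

#' Train the 3Di classification head on frozen encoder embeddings
#'
#' Two convolutional layers (embedding -> hidden -> 20 states) with a ReLU
#' between, trained by per-residue cross-entropy with Adam; embeddings are
#' never updated.
#'
#' @param embeddings list of `L_i x width` matrices from [encoder_embed()].
#' @param labels character vector of 3Di strings aligned to `embeddings`.
#' @param cfg a [head_config()].
#' @param quiet suppress log lines.
#' @return a `tdi_head` object.
#' @export
train_head <- function(embeddings, labels, cfg = head_config(),
                       quiet = FALSE) {
  stopifnot(length(embeddings) == length(labels))
  lens <- vapply(embeddings, nrow, integer(1))
  mism <- which(lens != nchar(labels))
  if (length(mism) > 0) {
    stop(sprintf("embedding/label length mismatch at record %d", mism[1]),
         call. = FALSE)
  }
  d <- ncol(embeddings[[1]]); k <- cfg$kernel_size; h <- cfg$hidden_channels
  y <- lapply(labels, function(s) match(split_chars(s), TDI_LETTERS))
  withr::with_seed(cfg$seed, {
    hp <- list(W1 = init_mat(k * d, h, 1 / sqrt(k * d)), b1 = rep(0, h),
               W2 = init_mat(k * h, 20L, 1 / sqrt(k * h)), b2 = rep(0, 20))
    opt <- adam_init(hp)
    n <- length(embeddings)
    losses <- numeric(0)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(n, b0 + cfg$batch_size - 1L)]
        grads <- new.env(parent = emptyenv())
        for (nm in names(hp)) grads[[nm]] <- hp[[nm]] * 0
        loss <- 0; ntok <- 0
        for (i in idx) {
          X <- embeddings[[i]]
          if (cfg$dropout > 0) {
            X <- X * (stats::runif(length(X)) >= cfg$dropout) /
              (1 - cfg$dropout)
          }
          fw <- head_forward(hp, X, k)
          t_i <- y[[i]]
          mx <- apply(fw$logits, 1, max)
          Z <- exp(fw$logits - mx); den <- rowSums(Z)
          loss <- loss - sum(fw$logits[cbind(seq_along(t_i), t_i)] - mx -
                               log(den))
          ntok <- ntok + length(t_i)
          P <- Z / den
          P[cbind(seq_along(t_i), t_i)] <- P[cbind(seq_along(t_i), t_i)] - 1
          dL <- P
          grads$W2 <- grads$W2 + crossprod(fw$U2, dL)
          grads$b2 <- grads$b2 + colSums(dL)
          dH <- fold_rows(dL %*% t(hp$W2), k, h) * (fw$H > 0)
          grads$W1 <- grads$W1 + crossprod(fw$U1, dH)
          grads$b1 <- grads$b1 + colSums(dH)
        }
        for (nm in names(hp)) grads[[nm]] <- grads[[nm]] / ntok
        st <- adam_step(hp, grads, opt, cfg$lr)
        hp <- st$p; opt <- st$opt
        losses <- c(losses, loss / ntok)
      }
      if (!quiet) flog("head epoch %d/%d loss %.3f", ep, cfg$epochs,
                       mean(utils::tail(losses, 20)))
    }
    structure(list(params = hp, kernel_size = k, hidden_channels = h,
                   width = d, losses = losses), class = "tdi_head")
  })
}

#' @export
print.tdi_head <- function(x, ...) {
  cat(sprintf("<tdi_head> kernel %d, %d hidden channels over width-%d embeddings\n",
              x$kernel_size, x$hidden_channels, x$width))
  invisible(x)
}

#' Predict 3Di states for an amino-acid sequence via the CNN head
#'
#' The fast inference path: encoder embeddings plus the convolutional head,
#' no autoregressive decoding. Residues whose maximum class probability falls
#' below `threshold` are flagged as low-confidence (`x` in `masked_labels`);
#' coverage is the unflagged fraction.
#'
#' @param model a `fold_model` (frozen encoder).
#' @param head a [train_head()] classifier.
#' @param aa_seq amino-acid string.
#' @param threshold confidence threshold in `[0, 1]` (0 keeps everything).
#' @return a `per_residue_prediction`: `labels` (argmax 3Di string),
#'   `masked_labels`, `probabilities` (`L x 20`, rows sum to 1),
#'   `confidence`, `masked`, `coverage`.
#' @export
predict_3di <- function(model, head, aa_seq, threshold = 0) {
  X <- encoder_embed(model, aa_seq, direction = "AA2fold")
  fw <- head_forward(head$params, X, head$kernel_size)
  mx <- apply(fw$logits, 1, max)
  Z <- exp(fw$logits - mx)
  P <- Z / rowSums(Z)
  colnames(P) <- TDI_LETTERS
  cls <- max.col(P, ties.method = "first")
  conf <- P[cbind(seq_len(nrow(P)), cls)]
  masked <- conf < threshold
  lab <- TDI_LETTERS[cls]
  mlab <- lab; mlab[masked] <- "x"
  structure(list(labels = paste(lab, collapse = ""),
                 masked_labels = paste(mlab, collapse = ""),
                 probabilities = P, confidence = conf, masked = masked,
                 coverage = mean(!masked)),
            class = "per_residue_prediction")
}

#' @export
print.per_residue_prediction <- function(x, ...) {
  cat(sprintf("<per_residue_prediction> %d residues, coverage %.2f\n",
              nrow(x$probabilities), x$coverage))
  cat(x$masked_labels, "\n")
  invisible(x)
}

#' Write 3Di predictions as FASTA plus a sidecar probability TSV
#'
#' Low-confidence residues appear as the placeholder `x`, keeping the output
#' aligned to the input; the TSV carries the full per-residue distributions.
#'
#' @param predictions named list of `per_residue_prediction` (names = ids).
#' @param fasta_path output 3Di FASTA.
#' @param probs_path optional TSV of per-residue probabilities.
#' @export
write_3di_predictions <- function(predictions, fasta_path,
                                  probs_path = NULL) {
  recs <- tibble::tibble(id = names(predictions),
                         tdi_seq = vapply(predictions, `[[`, character(1),
                                          "masked_labels"))
  write_fasta(recs, fasta_path, "3Di")
  if (!is.null(probs_path)) {
    tab <- purrr::imap_dfr(predictions, function(p, id) {
      out <- tibble::as_tibble(p$probabilities)
      out$id <- id; out$pos <- seq_len(nrow(p$probabilities))
      out$confidence <- p$confidence
      out
    })
    readr::write_tsv(tab, probs_path)
  }
  invisible(fasta_path)
}
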