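# Internal transformer math for the small encoder-decoder translation model.
#
# Architecture: tied input/output embedding, bidirectional encoder and
# autoregressive decoder with cross-attention. Blocks are pre-norm (RMSNorm),
# attention carries T5-style learned relative-position biases (shared bucket
# scheme, one bias table per layer), feed-forward is ReLU with hidden width
# 4d. Forward and backward passes are written out by hand on base matrix
# algebra; a finite-difference gradient check in the test suite guards the
# derivatives.
#
# Sequences in a batch are packed into one tall matrix for all position-wise
# operations (linear layers, norms, loss); attention runs per sequence on the
# packed rows.

RB_CLIP <- 8L
RB_NBUCKET <- 2L * RB_CLIP + 1L
LN_EPS <- 1e-6

rel_bucket_cache <- new.env(parent = emptyenv())

# Lq x Lk matrix of relative-offset buckets, clip(j - i, -8, 8) + 9.
rel_buckets <- function(Lq, Lk) {
  key <- paste0(Lq, "_", Lk)
  if (!is.null(rel_bucket_cache[[key]])) return(rel_bucket_cache[[key]])
  b <- outer(seq_len(Lq), seq_len(Lk), function(i, j)
    pmin(pmax(j - i, -RB_CLIP), RB_CLIP) + RB_CLIP + 1L)
  rel_bucket_cache[[key]] <- b
  b
}

rmsnorm_fwd <- function(X, g) {
  r <- sqrt(rowMeans(X * X) + LN_EPS)
  list(Y = (X / r) * rep(g, each = nrow(X)), r = r)
}

rmsnorm_bwd <- function(dY, X, g, r) {
  n <- ncol(X)
  dYg <- dY * rep(g, each = nrow(dY))
  dg <- colSums(dY * X / r)
  dX <- dYg / r - X * (rowSums(dYg * X) / (n * r^3))
  list(dX = dX, dg = dg)
}

softmax_rows <- function(S) {
  S <- S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S)
  E / rowSums(E)
}

init_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

# Parameter list for the encoder-decoder; V includes the whole vocabulary.
init_params <- function(V, d, n_layers, n_heads, seed = 1L) {
  withr::with_seed(seed, {
    p <- list(E = init_mat(V, d, 0.05))
    att <- function() init_mat(d, d, 1 / sqrt(d))
    ffn1 <- function() init_mat(d, 4 * d, 1 / sqrt(d))
    ffn2 <- function() init_mat(4 * d, d, 1 / sqrt(4 * d))
    for (l in seq_len(n_layers)) {
      pre <- paste0("enc", l, "_")
      p[[paste0(pre, "ln1")]] <- rep(1, d)
      p[[paste0(pre, "Wq")]] <- att(); p[[paste0(pre, "Wk")]] <- att()
      p[[paste0(pre, "Wv")]] <- att(); p[[paste0(pre, "Wo")]] <- att()
      p[[paste0(pre, "rb")]] <- matrix(0, n_heads, RB_NBUCKET)
      p[[paste0(pre, "ln2")]] <- rep(1, d)
      p[[paste0(pre, "W1")]] <- ffn1(); p[[paste0(pre, "b1")]] <- rep(0, 4 * d)
      p[[paste0(pre, "W2")]] <- ffn2(); p[[paste0(pre, "b2")]] <- rep(0, d)
    }
    p$enc_lnf <- rep(1, d)
    for (l in seq_len(n_layers)) {
      pre <- paste0("dec", l, "_")
      for (blk in c("s", "c")) {
        p[[paste0(pre, "ln", blk)]] <- rep(1, d)
        p[[paste0(pre, "Wq", blk)]] <- att(); p[[paste0(pre, "Wk", blk)]] <- att()
        p[[paste0(pre, "Wv", blk)]] <- att(); p[[paste0(pre, "Wo", blk)]] <- att()
        rb <- matrix(0, n_heads, RB_NBUCKET)
        if (blk == "c") {
          # locality prior: decoder position i is roughly aligned with
          # encoder position i+1 (the direction prefix shifts the source by
          # one); a mild initial bias there speeds up alignment discovery
          rb[, RB_CLIP + 2L] <- 2
        }
        p[[paste0(pre, "rb", blk)]] <- rb
      }
      p[[paste0(pre, "ln2")]] <- rep(1, d)
      p[[paste0(pre, "W1")]] <- ffn1(); p[[paste0(pre, "b1")]] <- rep(0, 4 * d)
      p[[paste0(pre, "W2")]] <- ffn2(); p[[paste0(pre, "b2")]] <- rep(0, d)
    }
    p$dec_lnf <- rep(1, d)
    p
  })
}

# --- attention ---------------------------------------------------------------

# Multi-head attention for one sequence pair of packed rows.
# Q rows attend to K/V rows; mask: "none" or "causal". Returns output rows and
# the per-head probability matrices (needed for backward).
mha_fwd <- function(Qp, Kp, Vp, rb, n_heads, mask = "none") {
  Lq <- nrow(Qp); Lk <- nrow(Kp); dh <- ncol(Qp) / n_heads
  out <- matrix(0, Lq, ncol(Qp))
  Ps <- vector("list", n_heads)
  bk <- rel_buckets(Lq, Lk)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(Qp[, cols, drop = FALSE], Kp[, cols, drop = FALSE]) / sqrt(dh)
    S <- S + matrix(rb[h, bk], Lq, Lk)
    if (mask == "causal") S[upper.tri(S)] <- -Inf
    P <- softmax_rows(S)
    Ps[[h]] <- P
    out[, cols] <- P %*% Vp[, cols, drop = FALSE]
  }
  list(out = out, Ps = Ps)
}

mha_bwd <- function(dOut, Qp, Kp, Vp, Ps, rb, n_heads) {
  Lq <- nrow(Qp); Lk <- nrow(Kp); dh <- ncol(Qp) / n_heads
  dQ <- matrix(0, Lq, ncol(Qp)); dK <- matrix(0, Lk, ncol(Kp))
  dV <- matrix(0, Lk, ncol(Vp)); drb <- matrix(0, n_heads, RB_NBUCKET)
  bk <- rel_buckets(Lq, Lk)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    P <- Ps[[h]]
    dO <- dOut[, cols, drop = FALSE]
    dP <- tcrossprod(dO, Vp[, cols, drop = FALSE])
    dV[, cols] <- crossprod(P, dO)
    dS <- P * (dP - rowSums(dP * P))
    dQ[, cols] <- dS %*% Kp[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- crossprod(dS, Qp[, cols, drop = FALSE]) / sqrt(dh)
    sums <- rowsum(as.numeric(dS), as.numeric(bk))
    vals <- numeric(RB_NBUCKET)
    vals[as.integer(rownames(sums))] <- sums
    drb[h, ] <- drb[h, ] + vals
  }
  list(dQ = dQ, dK = dK, dV = dV, drb = drb)
}

# --- packed-batch forward / backward ----------------------------------------

# ids_list: list of 0-based token id vectors. Returns packing bookkeeping.
pack_ids <- function(ids_list) {
  lens <- vapply(ids_list, length, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  list(ids = unlist(ids_list) + 1L, lens = lens,
       rows = purrr::map2(starts, ends, ~ seq.int(.x, .y)))
}

# One stack (encoder or decoder) forward over packed rows.
# kind = "enc" or "dec"; for "dec", enc_out/enc_rows supply cross-attention.
stack_fwd <- function(p, cfg, X, rows, kind, enc_out = NULL, enc_rows = NULL,
                      keep_cache = FALSE) {
  n_heads <- cfg$n_heads
  cache <- list()
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0(kind, l, "_")
    blocks <- if (kind == "enc") list(c("", "none")) else
      list(c("s", "causal"), c("c", "cross"))
    for (blk in blocks) {
      sfx <- blk[1]; mode <- blk[2]
      ln_name <- if (kind == "enc") paste0(pre, "ln1") else paste0(pre, "ln", sfx)
      nrm <- rmsnorm_fwd(X, p[[ln_name]])
      Q <- nrm$Y %*% p[[paste0(pre, "Wq", sfx)]]
      if (mode == "cross") {
        KV_in <- enc_out; kv_rows <- enc_rows
      } else {
        KV_in <- nrm$Y; kv_rows <- rows
      }
      K <- KV_in %*% p[[paste0(pre, "Wk", sfx)]]
      V <- KV_in %*% p[[paste0(pre, "Wv", sfx)]]
      O <- matrix(0, nrow(X), ncol(X))
      Ps <- vector("list", length(rows))
      for (s in seq_along(rows)) {
        r <- rows[[s]]; rk <- kv_rows[[s]]
        att <- mha_fwd(Q[r, , drop = FALSE], K[rk, , drop = FALSE],
                       V[rk, , drop = FALSE], p[[paste0(pre, "rb", sfx)]],
                       n_heads, mask = if (mode == "causal") "causal" else "none")
        O[r, ] <- att$out
        Ps[[s]] <- att$Ps
      }
      Att <- O %*% p[[paste0(pre, "Wo", sfx)]]
      if (keep_cache) {
        cache[[paste0(pre, sfx)]] <- list(Xin = X, nrm = nrm, Q = Q, K = K,
                                          V = V, O = O, Ps = Ps)
      }
      X <- X + Att
    }
    nrm2 <- rmsnorm_fwd(X, p[[paste0(pre, "ln2")]])
    H1 <- nrm2$Y %*% p[[paste0(pre, "W1")]]
    H1 <- sweep(H1, 2, p[[paste0(pre, "b1")]], "+")
    H1r <- pmax(H1, 0)
    FF <- sweep(H1r %*% p[[paste0(pre, "W2")]], 2, p[[paste0(pre, "b2")]], "+")
    if (keep_cache) {
      cache[[paste0(pre, "ffn")]] <- list(Xin = X, nrm = nrm2, H1r = H1r)
    }
    X <- X + FF
  }
  lnf <- paste0(kind, "_lnf")
  nrmf <- rmsnorm_fwd(X, p[[lnf]])
  if (keep_cache) cache[[lnf]] <- list(Xin = X, nrm = nrmf)
  list(H = nrmf$Y, cache = cache)
}

# Backward through one stack. dH is the gradient at the stack output.
# Returns gradient w.r.t. the stack input embedding rows, accumulates into
# `grads` (an environment), and returns d(enc_out) contributions for decoders.
stack_bwd <- function(p, cfg, dH, rows, kind, cache, grads,
                      enc_out = NULL, enc_rows = NULL) {
  n_heads <- cfg$n_heads
  add_grad <- function(name, val) {
    grads[[name]] <- if (is.null(grads[[name]])) val else grads[[name]] + val
  }
  lnf <- paste0(kind, "_lnf")
  cf <- cache[[lnf]]
  bw <- rmsnorm_bwd(dH, cf$Xin, p[[lnf]], cf$nrm$r)
  dX <- bw$dX
  add_grad(lnf, bw$dg)
  dEnc <- if (kind == "dec") matrix(0, nrow(enc_out), ncol(enc_out)) else NULL

  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- paste0(kind, l, "_")
    # FFN block
    cf <- cache[[paste0(pre, "ffn")]]
    dFF <- dX
    dH1r <- dFF %*% t(p[[paste0(pre, "W2")]])
    add_grad(paste0(pre, "W2"), crossprod(cf$H1r, dFF))
    add_grad(paste0(pre, "b2"), colSums(dFF))
    dH1 <- dH1r * (cf$H1r > 0)
    add_grad(paste0(pre, "W1"), crossprod(cf$nrm$Y, dH1))
    add_grad(paste0(pre, "b1"), colSums(dH1))
    dNrm <- dH1 %*% t(p[[paste0(pre, "W1")]])
    bw <- rmsnorm_bwd(dNrm, cf$Xin, p[[paste0(pre, "ln2")]], cf$nrm$r)
    add_grad(paste0(pre, "ln2"), bw$dg)
    dX <- dX + bw$dX

    blocks <- if (kind == "enc") list(c("", "none")) else
      list(c("c", "cross"), c("s", "causal"))
    for (blk in blocks) {
      sfx <- blk[1]; mode <- blk[2]
      cf <- cache[[paste0(pre, sfx)]]
      dAtt <- dX
      dO <- dAtt %*% t(p[[paste0(pre, "Wo", sfx)]])
      add_grad(paste0(pre, "Wo", sfx), crossprod(cf$O, dAtt))
      kv_rows <- if (mode == "cross") enc_rows else rows
      dQ <- matrix(0, nrow(cf$Q), ncol(cf$Q))
      dK <- matrix(0, nrow(cf$K), ncol(cf$K))
      dV <- matrix(0, nrow(cf$V), ncol(cf$V))
      drb <- matrix(0, n_heads, RB_NBUCKET)
      for (s in seq_along(rows)) {
        r <- rows[[s]]; rk <- kv_rows[[s]]
        bwa <- mha_bwd(dO[r, , drop = FALSE], cf$Q[r, , drop = FALSE],
                       cf$K[rk, , drop = FALSE], cf$V[rk, , drop = FALSE],
                       cf$Ps[[s]], p[[paste0(pre, "rb", sfx)]], n_heads)
        dQ[r, ] <- dQ[r, ] + bwa$dQ
        dK[rk, ] <- dK[rk, ] + bwa$dK
        dV[rk, ] <- dV[rk, ] + bwa$dV
        drb <- drb + bwa$drb
      }
      add_grad(paste0(pre, "rb", sfx), drb)
      dNrmQ <- dQ %*% t(p[[paste0(pre, "Wq", sfx)]])
      add_grad(paste0(pre, "Wq", sfx), crossprod(cf$nrm$Y, dQ))
      KV_in <- if (mode == "cross") enc_out else cf$nrm$Y
      add_grad(paste0(pre, "Wk", sfx), crossprod(KV_in, dK))
      add_grad(paste0(pre, "Wv", sfx), crossprod(KV_in, dV))
      dKV_in <- dK %*% t(p[[paste0(pre, "Wk", sfx)]]) +
        dV %*% t(p[[paste0(pre, "Wv", sfx)]])
      if (mode == "cross") {
        dEnc <- dEnc + dKV_in
        dNrm <- dNrmQ
      } else {
        dNrm <- dNrmQ + dKV_in
      }
      ln_name <- if (kind == "enc") paste0(pre, "ln1") else paste0(pre, "ln", sfx)
      bw <- rmsnorm_bwd(dNrm, cf$Xin, p[[ln_name]], cf$nrm$r)
      add_grad(ln_name, bw$dg)
      dX <- dX + bw$dX
    }
  }
  list(dX = dX, dEnc = dEnc)
}

# Full teacher-forced forward+backward: cross-entropy over the packed decoder
# targets. Returns loss (mean per token), token accuracy, and gradients.
seq2seq_loss <- function(p, cfg, enc_ids, dec_in_ids, dec_tgt_ids,
                         want_grads = TRUE) {
  pe <- pack_ids(enc_ids)
  pd <- pack_ids(dec_in_ids)
  tgt <- unlist(dec_tgt_ids) + 1L
  Xe <- p$E[pe$ids, , drop = FALSE]
  enc <- stack_fwd(p, cfg, Xe, pe$rows, "enc", keep_cache = want_grads)
  Xd <- p$E[pd$ids, , drop = FALSE]
  dec <- stack_fwd(p, cfg, Xd, pd$rows, "dec", enc_out = enc$H,
                   enc_rows = pe$rows, keep_cache = want_grads)
  logits <- tcrossprod(dec$H, p$E)
  mx <- logits[cbind(seq_len(nrow(logits)), max.col(logits, ties.method = "first"))]
  Z <- exp(logits - mx)
  denom <- rowSums(Z)
  n_tok <- length(tgt)
  logp <- (logits[cbind(seq_len(n_tok), tgt)] - mx) - log(denom)
  loss <- -mean(logp)
  acc <- mean(max.col(logits, ties.method = "first") == tgt)
  if (!want_grads) return(list(loss = loss, accuracy = acc, n_tok = n_tok))

  Pmat <- Z / denom
  Pmat[cbind(seq_len(n_tok), tgt)] <- Pmat[cbind(seq_len(n_tok), tgt)] - 1
  dLogits <- Pmat / n_tok
  grads <- new.env(parent = emptyenv())
  dHdec <- dLogits %*% p$E
  dE_out <- crossprod(dLogits, dec$H)
  bwd <- stack_bwd(p, cfg, dHdec, pd$rows, "dec", dec$cache, grads,
                   enc_out = enc$H, enc_rows = pe$rows)
  bwe <- stack_bwd(p, cfg, bwd$dEnc, pe$rows, "enc", enc$cache, grads)
  dE <- dE_out
  dE_dec <- rowsum(bwd$dX, pd$ids)
  dE[as.integer(rownames(dE_dec)), ] <-
    dE[as.integer(rownames(dE_dec)), ] + dE_dec
  dE_enc <- rowsum(bwe$dX, pe$ids)
  dE[as.integer(rownames(dE_enc)), ] <-
    dE[as.integer(rownames(dE_enc)), ] + dE_enc
  grads$E <- dE
  list(loss = loss, accuracy = acc, n_tok = n_tok, grads = grads)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(p) {
  list(m = purrr::map(p, ~ .x * 0), v = purrr::map(p, ~ .x * 0), t = 0L)
}

adam_step <- function(p, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 1) {
  opt$t <- opt$t + 1L
  gnames <- ls(grads)
  # global gradient-norm clipping
  gn <- sqrt(sum(vapply(gnames, function(nm) sum(grads[[nm]]^2), numeric(1))))
  scale <- if (gn > clip) clip / gn else 1
  for (nm in gnames) {
    g <- grads[[nm]] * scale
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, opt = opt)
}

# --- inference helpers -------------------------------------------------------

# Encoder forward for a single id vector; returns the L x d hidden matrix.
encode_hidden <- function(p, cfg, ids) {
  X <- p$E[ids + 1L, , drop = FALSE]
  stack_fwd(p, cfg, X, list(seq_along(ids)), "enc")$H
}

# Decoder forward over a full prefix; returns logits at the last position.
decoder_last_logits <- function(p, cfg, dec_ids, enc_H) {
  X <- p$E[dec_ids + 1L, , drop = FALSE]
  H <- stack_fwd(p, cfg, X, list(seq_along(dec_ids)), "dec",
                 enc_out = enc_H, enc_rows = list(seq_len(nrow(enc_H))))$H
  as.numeric(tcrossprod(H[nrow(H), , drop = FALSE], p$E))
}
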