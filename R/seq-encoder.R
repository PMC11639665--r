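# BERT-style transformer encoder over k-mer tokens. Pre-training predicts
# masked k-mers (MLM); after training, the CLS hidden state is the pooled
# per-molecule sequence embedding S. Forward passes cache intermediates so
# the hand-written backward pass can run; both are exercised by
# finite-difference gradient tests.

seq_init_params <- function(cfg) {
  d <- cfg$dim; f <- cfg$ffn; V <- cfg$vocab_size
  par <- list(
    tok_emb = nn_init_mat(V, d, sd = 0.02),
    pos_emb = nn_init_mat(cfg$max_len, d, sd = 0.02))
  for (l in seq_len(cfg$layers)) {
    p <- function(nm) paste0("L", l, ".", nm)
    par[[p("Wq")]] <- nn_init_mat(d, d); par[[p("bq")]] <- numeric(d)
    par[[p("Wk")]] <- nn_init_mat(d, d); par[[p("bk")]] <- numeric(d)
    par[[p("Wv")]] <- nn_init_mat(d, d); par[[p("bv")]] <- numeric(d)
    par[[p("Wo")]] <- nn_init_mat(d, d); par[[p("bo")]] <- numeric(d)
    par[[p("ln1_g")]] <- rep(1, d); par[[p("ln1_b")]] <- numeric(d)
    par[[p("W1")]] <- nn_init_mat(d, f); par[[p("b1")]] <- numeric(f)
    par[[p("W2")]] <- nn_init_mat(f, d); par[[p("b2")]] <- numeric(d)
    par[[p("ln2_g")]] <- rep(1, d); par[[p("ln2_b")]] <- numeric(d)
  }
  par$mlm_W <- nn_init_mat(d, V)
  par$mlm_b <- numeric(V)
  par
}

# Forward pass over one tokenized sequence. ids are 0-based vocabulary ids.
seq_forward <- function(par, cfg, ids, mask, keep_cache = TRUE) {
  Tn <- length(ids)
  if (any(ids >= cfg$vocab_size)) abort("token id outside vocabulary")
  if (Tn > nrow(par$pos_emb)) abort("sequence longer than position table")
  X <- par$tok_emb[ids + 1, , drop = FALSE] +
    par$pos_emb[seq_len(Tn), , drop = FALSE]
  h <- cfg$heads; d <- cfg$dim; dh <- d %/% h
  masked_cols <- which(mask == 0)
  caches <- if (keep_cache) vector("list", cfg$layers) else NULL
  for (l in seq_len(cfg$layers)) {
    p <- function(nm) par[[paste0("L", l, ".", nm)]]
    X_in <- X
    Q <- add_bias(X %*% p("Wq"), p("bq"))
    K <- add_bias(X %*% p("Wk"), p("bk"))
    V <- add_bias(X %*% p("Wv"), p("bv"))
    O <- matrix(0, Tn, d)
    A_heads <- vector("list", h)
    for (i in seq_len(h)) {
      idx <- ((i - 1) * dh + 1):(i * dh)
      sc <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
      if (length(masked_cols) > 0) sc[, masked_cols] <- -Inf
      A <- row_softmax(sc)
      O[, idx] <- A %*% V[, idx, drop = FALSE]
      A_heads[[i]] <- A
    }
    M <- add_bias(O %*% p("Wo"), p("bo"))
    ln1 <- layernorm_fwd(X_in + M, p("ln1_g"), p("ln1_b"))
    X1 <- ln1$y
    F1 <- nn_relu(add_bias(X1 %*% p("W1"), p("b1")))
    F2 <- add_bias(F1 %*% p("W2"), p("b2"))
    ln2 <- layernorm_fwd(X1 + F2, p("ln2_g"), p("ln2_b"))
    X <- ln2$y
    if (keep_cache) {
      caches[[l]] <- list(X_in = X_in, Q = Q, K = K, V = V, A = A_heads,
                          O = O, ln1 = ln1, X1 = X1, F1 = F1, ln2 = ln2)
    }
  }
  list(H = X, caches = caches, ids = ids, attn = if (keep_cache) NULL else NULL)
}

# Backward pass; dH is the gradient at the final hidden states (T x d).
# Returns a grad list over the sequence-encoder parameters (embeddings and
# layers only; MLM head grads are handled by the caller).
seq_backward <- function(par, cfg, fwd, dH) {
  h <- cfg$heads; d <- cfg$dim; dh <- d %/% h
  ids <- fwd$ids; Tn <- length(ids)
  g <- list()
  gadd <- function(nm, val) {
    g[[nm]] <<- if (is.null(g[[nm]])) val else g[[nm]] + val
  }
  dX <- dH
  for (l in rev(seq_len(cfg$layers))) {
    cc <- fwd$caches[[l]]
    pn <- function(nm) paste0("L", l, ".", nm)
    p <- function(nm) par[[pn(nm)]]
    lb2 <- layernorm_bwd(cc$ln2, p("ln2_g"), dX)
    gadd(pn("ln2_g"), lb2$dg); gadd(pn("ln2_b"), lb2$db)
    dX1 <- lb2$dx
    dF2 <- lb2$dx
    gadd(pn("W2"), crossprod(cc$F1, dF2)); gadd(pn("b2"), colSums(dF2))
    dF1 <- tcrossprod(dF2, p("W2"))
    dF1[cc$F1 <= 0] <- 0
    gadd(pn("W1"), crossprod(cc$X1, dF1)); gadd(pn("b1"), colSums(dF1))
    dX1 <- dX1 + tcrossprod(dF1, p("W1"))
    lb1 <- layernorm_bwd(cc$ln1, p("ln1_g"), dX1)
    gadd(pn("ln1_g"), lb1$dg); gadd(pn("ln1_b"), lb1$db)
    dX <- lb1$dx          # gradient into the residual branch (X_in)
    dM <- lb1$dx
    gadd(pn("Wo"), crossprod(cc$O, dM)); gadd(pn("bo"), colSums(dM))
    dO <- tcrossprod(dM, p("Wo"))
    dQ <- matrix(0, Tn, d); dK <- matrix(0, Tn, d); dV <- matrix(0, Tn, d)
    for (i in seq_len(h)) {
      idx <- ((i - 1) * dh + 1):(i * dh)
      A <- cc$A[[i]]
      dOh <- dO[, idx, drop = FALSE]
      dA <- tcrossprod(dOh, cc$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(A, dOh)
      dSc <- row_softmax_bwd(A, dA) / sqrt(dh)
      dQ[, idx] <- dSc %*% cc$K[, idx, drop = FALSE]
      dK[, idx] <- crossprod(dSc, cc$Q[, idx, drop = FALSE])
    }
    gadd(pn("Wq"), crossprod(cc$X_in, dQ)); gadd(pn("bq"), colSums(dQ))
    gadd(pn("Wk"), crossprod(cc$X_in, dK)); gadd(pn("bk"), colSums(dK))
    gadd(pn("Wv"), crossprod(cc$X_in, dV)); gadd(pn("bv"), colSums(dV))
    dX <- dX + tcrossprod(dQ, p("Wq")) + tcrossprod(dK, p("Wk")) +
      tcrossprod(dV, p("Wv"))
  }
  dtok <- matrix(0, cfg$vocab_size, d)
  acc <- rowsum(dX, group = ids)
  dtok[as.integer(rownames(acc)) + 1, ] <- acc
  g$tok_emb <- dtok
  dpos <- matrix(0, nrow(par$pos_emb), d)
  dpos[seq_len(Tn), ] <- dX
  g$pos_emb <- dpos
  g
}

# Pool the final hidden states into the molecule embedding S.
seq_pool <- function(H, mask, pooling = "cls") {
  if (pooling == "cls") H[1, ] else colMeans(H[mask == 1, , drop = FALSE])
}

# Distribute a gradient on S back onto the hidden states.
seq_pool_bwd <- function(dS, Tn, mask, pooling = "cls") {
  dH <- matrix(0, Tn, length(dS))
  if (pooling == "cls") {
    dH[1, ] <- dS
  } else {
    real <- which(mask == 1)
    dH[real, ] <- matrix(dS / length(real), length(real), length(dS), byrow = TRUE)
  }
  dH
}

#' Mean masked-language-model cross-entropy
#'
#' Mean of `-log softmax(logits)[label]` over positions whose label is not
#' the ignore marker. Logits at ignored positions never affect the value.
#'
#' @param logits `n x V` matrix of unnormalized scores, one row per position.
#' @param labels Integer vector of 0-based true token ids, with `ignore_index`
#'   marking unselected positions.
#' @param ignore_index Label value to skip (default -1).
#' @return Nonnegative scalar loss.
#' @export
mlm_loss <- function(logits, labels, ignore_index = -1L) {
  sel <- which(labels != ignore_index)
  if (length(sel) == 0) abort("no selected positions: MLM loss undefined")
  lg <- logits[sel, , drop = FALSE]
  m <- apply(lg, 1, max)
  lse <- m + log(rowSums(exp(lg - m)))
  mean(lse - lg[cbind(seq_along(sel), labels[sel] + 1)])
}

# MLM loss + gradient at the selected hidden rows for one sequence.
# Returns loss-sum (not mean), n positions, dH contribution and head grads.
mlm_head_fwd_bwd <- function(par, H, labels) {
  sel <- which(labels != MLM_IGNORE)
  n <- length(sel)
  if (n == 0) {
    return(list(loss_sum = 0, n = 0, dH = NULL, gW = NULL, gb = NULL))
  }
  Hs <- H[sel, , drop = FALSE]
  logits <- add_bias(Hs %*% par$mlm_W, par$mlm_b)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  P <- e / rowSums(e)
  tgt <- cbind(seq_len(n), labels[sel] + 1)
  loss_sum <- sum(log(rowSums(e)) + m - logits[tgt])
  dlogits <- P
  dlogits[tgt] <- dlogits[tgt] - 1      # d(sum CE)/dlogits
  dH <- matrix(0, nrow(H), ncol(H))
  dH[sel, ] <- tcrossprod(dlogits, par$mlm_W)
  list(loss_sum = loss_sum, n = n, dH = dH,
       gW = crossprod(Hs, dlogits), gb = colSums(dlogits))
}
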