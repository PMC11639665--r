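# Objective machinery: symmetric InfoNCE contrastive alignment of the two
# modality embeddings, ReLU projection of each modality into a shared latent
# space, softmax attention fusion over the modality tokens, cross-entropy
# classification, and the weighted total loss alpha * L_cls + beta * L_con.

l2_normalize_rows <- function(X) {
  nrm <- sqrt(rowSums(X * X))
  if (any(nrm == 0)) abort("zero-norm embedding row: cannot normalize")
  list(Xn = X / nrm, nrm = nrm)
}

#' Symmetric InfoNCE contrastive loss
#'
#' Rows of `S` and `G` are L2-normalized; with similarity matrix
#' `M = S_hat %*% t(G_hat)`, the sequence-to-structure direction is the mean
#' over molecules of `-log softmax(M_i / delta)[i]` and the
#' structure-to-sequence direction uses the transpose. The returned loss is
#' the average of the two directions: matched sequence/structure pairs are
#' pulled together, mismatched pairs pushed apart.
#'
#' @param S,G `N x d` embedding matrices (matched rows are positives).
#' @param delta Temperature, positive; default 0.1.
#' @return Nonnegative scalar; exactly 0 for `N = 1` and `ln N` when all
#'   similarities are equal.
#' @export
contrastive_loss <- function(S, G, delta = 0.1) {
  contrastive_loss_grad(S, G, delta)$loss
}

# Loss plus gradients with respect to the unnormalized S and G.
contrastive_loss_grad <- function(S, G, delta = 0.1) {
  if (!is.numeric(delta) || delta <= 0) abort("temperature delta must be > 0")
  S <- rbind(S); G <- rbind(G)
  N <- nrow(S)
  if (nrow(G) != N || ncol(G) != ncol(S)) abort("S and G must share shape")
  sn <- l2_normalize_rows(S); gn <- l2_normalize_rows(G)
  M <- tcrossprod(sn$Xn, gn$Xn)
  P <- row_softmax(M / delta)            # sequence -> structure
  Q <- row_softmax(t(M) / delta)         # structure -> sequence
  di <- cbind(seq_len(N), seq_len(N))
  loss <- (mean(-log(P[di])) + mean(-log(Q[di]))) / 2
  dM <- (P - diag(N) + t(Q - diag(N))) / (2 * N * delta)
  dSn <- dM %*% gn$Xn
  dGn <- crossprod(dM, sn$Xn)
  bwd_norm <- function(Xn, nrm, dXn) (dXn - Xn * rowSums(Xn * dXn)) / nrm
  list(loss = loss,
       dS = bwd_norm(sn$Xn, sn$nrm, dSn),
       dG = bwd_norm(gn$Xn, gn$nrm, dGn))
}

#' Project both modalities into the shared latent space
#'
#' Each modality gets its own linear map followed by ReLU, producing two
#' modality tokens per molecule that live in the same space and can be
#' attended over by [attention_fuse()].
#'
#' @param S,G `N x d` embedding matrices.
#' @param W_s,W_g `d x d_z` projection matrices.
#' @return List with `z_seq` and `z_struct`, both `N x d_z`.
#' @export
project_shared <- function(S, G, W_s, W_g) {
  S <- rbind(S); G <- rbind(G)
  if (ncol(S) != nrow(W_s) || ncol(G) != nrow(W_g)) {
    abort("projection dimension mismatch")
  }
  list(z_seq = nn_relu(S %*% W_s), z_struct = nn_relu(G %*% W_g))
}

#' Attention fusion of shared-space tokens
#'
#' Scores each token by its dot product with the attention weight vector,
#' softmaxes the scores into convex weights, and returns the weighted sum.
#' The output always lies in the convex hull of the tokens.
#'
#' @param tokens A list of length-`d_z` vectors, or an `n x d_z` matrix with
#'   one token per row.
#' @param w_alpha Length-`d_z` attention weight vector.
#' @return List with `fused` (length-`d_z` vector) and `alpha` (softmax
#'   weights, nonnegative, summing to 1).
#' @export
attention_fuse <- function(tokens, w_alpha) {
  if (is.list(tokens)) tokens <- do.call(rbind, tokens)
  tokens <- rbind(tokens)
  if (nrow(tokens) == 0) abort("attention_fuse needs at least one token")
  scores <- as.numeric(tokens %*% w_alpha)
  alpha <- as.numeric(row_softmax(matrix(scores, 1)))
  list(fused = as.numeric(crossprod(tokens, alpha)), alpha = alpha)
}

#' Cross-entropy classification loss from probabilities
#'
#' Mean over the batch of `-log p(true class)`.
#'
#' @param probs `N x C` matrix of class probabilities (rows sum to 1).
#' @param labels Integer class indices in `1..C` (or a factor).
#' @return Nonnegative scalar.
#' @export
classification_loss <- function(probs, labels) {
  probs <- rbind(probs)
  if (is.factor(labels)) labels <- as.integer(labels)
  if (any(labels < 1 | labels > ncol(probs))) abort("label out of range")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    abort("probability rows must sum to 1")
  }
  mean(-log(probs[cbind(seq_len(nrow(probs)), labels)]))
}

#' Weighted total training loss
#'
#' `alpha * L_classification + beta * L_contrastive`, with the constraint
#' `alpha + beta = 1` enforced.
#'
#' @param l_cls Classification loss.
#' @param l_con Contrastive loss.
#' @param alpha,beta Loss weights in `[0, 1]` with `alpha + beta == 1`.
#'   Default `alpha = 0.8`.
#' @return Scalar total loss.
#' @export
total_loss <- function(l_cls, l_con, alpha = 0.8, beta = 1 - alpha) {
  check_alpha_beta(alpha, beta)
  alpha * l_cls + beta * l_con
}

check_alpha_beta <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      alpha < 0 || beta < 0 || alpha > 1 || beta > 1 ||
      abs(alpha + beta - 1) > 1e-8) {
    abort("loss weights must satisfy alpha + beta = 1 with alpha, beta in [0, 1]")
  }
  invisible(TRUE)
}

# ---- fused head used in training ------------------------------------------

fusion_init_params <- function(cfg) {
  d <- cfg$dim; dz <- cfg$dz; C <- cfg$n_classes
  cls_in <- if (cfg$fusion_mode == "concat") 2 * dz else dz
  list(
    Ws = nn_init_mat(d, dz),
    Wg = nn_init_mat(d, dz),
    w_alpha = rnorm(dz, sd = 0.02),
    C1 = nn_init_mat(cls_in, dz), c1_b = numeric(dz),
    C2 = nn_init_mat(dz, C), c2_b = numeric(C))
}

# Forward through projection + fusion + MLP classifier for a batch.
# modalities: "both", "seq" (z_struct dropped), "struct" (z_seq dropped).
fusion_forward <- function(par, cfg, S, G) {
  N <- nrow(S)
  zs <- S %*% par$Ws; zg <- G %*% par$Wg
  z_seq <- nn_relu(zs); z_struct <- nn_relu(zg)
  mode <- cfg$fusion_mode
  use_s <- cfg$modalities %in% c("both", "seq")
  use_g <- cfg$modalities %in% c("both", "struct")
  if (use_s && use_g) {
    if (mode == "attention") {
      sc <- cbind(z_seq %*% par$w_alpha, z_struct %*% par$w_alpha)
      Al <- row_softmax(sc)
      Z <- Al[, 1] * z_seq + Al[, 2] * z_struct
    } else if (mode == "sum") {
      Z <- nn_relu(zs + zg)              # literal shared projection of the sum
      Al <- NULL
    } else {                             # concat
      Z <- cbind(z_seq, z_struct)
      Al <- NULL
    }
  } else if (use_s) {
    Z <- z_seq; Al <- NULL
  } else {
    Z <- z_struct; Al <- NULL
  }
  h1 <- nn_relu(add_bias(Z %*% par$C1, par$c1_b))
  logits <- add_bias(h1 %*% par$C2, par$c2_b)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, logits = logits, h1 = h1, Z = Z, Al = Al,
       z_seq = z_seq, z_struct = z_struct, zs = zs, zg = zg,
       use_s = use_s, use_g = use_g)
}

# Backward from mean cross-entropy; labels are 1-based class indices.
# Returns grads for fusion params plus dS, dG feeding the encoders.
fusion_backward <- function(par, cfg, fwd, S, G, labels, loss_scale = 1) {
  N <- nrow(fwd$probs)
  dlogits <- fwd$probs
  dlogits[cbind(seq_len(N), labels)] <- dlogits[cbind(seq_len(N), labels)] - 1
  dlogits <- dlogits * (loss_scale / N)
  g <- list()
  g$C2 <- crossprod(fwd$h1, dlogits); g$c2_b <- colSums(dlogits)
  dh1 <- tcrossprod(dlogits, par$C2)
  dh1[fwd$h1 <= 0] <- 0
  g$C1 <- crossprod(fwd$Z, dh1); g$c1_b <- colSums(dh1)
  dZ <- tcrossprod(dh1, par$C1)
  dz_seq <- matrix(0, N, cfg$dz); dz_struct <- matrix(0, N, cfg$dz)
  g$w_alpha <- numeric(cfg$dz)
  mode <- cfg$fusion_mode
  if (fwd$use_s && fwd$use_g) {
    if (mode == "attention") {
      Al <- fwd$Al
      dz_seq <- Al[, 1] * dZ
      dz_struct <- Al[, 2] * dZ
      dAl <- cbind(rowSums(dZ * fwd$z_seq), rowSums(dZ * fwd$z_struct))
      ds <- row_softmax_bwd(Al, dAl)
      dz_seq <- dz_seq + outer(ds[, 1], par$w_alpha)
      dz_struct <- dz_struct + outer(ds[, 2], par$w_alpha)
      g$w_alpha <- as.numeric(crossprod(fwd$z_seq, ds[, 1]) +
                              crossprod(fwd$z_struct, ds[, 2]))
      dzs <- dz_seq; dzs[fwd$z_seq <= 0] <- 0
      dzg <- dz_struct; dzg[fwd$z_struct <= 0] <- 0
    } else if (mode == "sum") {
      dZpre <- dZ; dZpre[fwd$Z <= 0] <- 0
      dzs <- dZpre; dzg <- dZpre
    } else {                             # concat
      dz_seq <- dZ[, seq_len(cfg$dz), drop = FALSE]
      dz_struct <- dZ[, cfg$dz + seq_len(cfg$dz), drop = FALSE]
      dzs <- dz_seq; dzs[fwd$z_seq <= 0] <- 0
      dzg <- dz_struct; dzg[fwd$z_struct <= 0] <- 0
    }
  } else if (fwd$use_s) {
    dzs <- dZ; dzs[fwd$z_seq <= 0] <- 0
    dzg <- matrix(0, N, cfg$dz)
  } else {
    dzg <- dZ; dzg[fwd$z_struct <= 0] <- 0
    dzs <- matrix(0, N, cfg$dz)
  }
  g$Ws <- crossprod(S, dzs)
  g$Wg <- crossprod(G, dzg)
  list(grads = g,
       dS = tcrossprod(dzs, par$Ws),
       dG = tcrossprod(dzg, par$Wg))
}
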