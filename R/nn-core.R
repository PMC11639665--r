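# Minimal neural-network kernels in base R matrix code: parameter containers
# are flat named lists of matrices/vectors; every forward pass has a matching
# hand-written backward pass (validated by finite-difference tests), and
# optimization is Adam with decoupled weight decay. Everything is driven by
# R's RNG, so a single set.seed() makes whole runs bit-reproducible.

# Glorot-scaled normal init by default (embeddings pass sd explicitly).
nn_init_mat <- function(nr, nc, sd = sqrt(2 / (nr + nc))) {
  matrix(rnorm(nr * nc, sd = sd), nr, nc)
}

nn_relu <- function(x) { x[x < 0] <- 0; x }

# Row-wise softmax; rows may contain -Inf (masked) but need one finite entry.
row_softmax <- function(z) {
  m <- apply(z, 1, max)
  if (any(!is.finite(m))) abort("softmax row with all entries masked")
  e <- exp(z - m)
  e / rowSums(e)
}

# Backward through row softmax: dz = p * (dp - rowSums(dp * p))
row_softmax_bwd <- function(p, dp) p * (dp - rowSums(dp * p))

# Add a row vector to every row of a matrix.
add_bias <- function(X, b) X + rep(b, each = nrow(X))

# Row-wise layer normalization with learnable gain/offset.
layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = add_bias(xhat * rep(g, each = nrow(x)), b), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(cache, g, dy) {
  xhat <- cache$xhat
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# Gradient accumulator over a flat named parameter list.
grad_zero <- function(params) lapply(params, function(p) p * 0)

grad_add <- function(acc, g) {
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

grad_scale <- function(g, s) lapply(g, function(x) x * s)

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# Adam with decoupled weight decay (applied to matrices, not bias vectors or
# layer-norm gains: names ending in _b, _g or containing "bias" are exempt).
# lr may be a scalar or a named vector/list giving a per-parameter rate.
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  scalar_lr <- length(lr) == 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    lr_i <- if (scalar_lr) lr else lr[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr_i * upd
    if (weight_decay > 0 && is.matrix(params[[nm]])) {
      params[[nm]] <- params[[nm]] - lr_i * weight_decay * params[[nm]]
    }
  }
  list(params = params, state = state)
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V`, with padded key positions excluded
#' from the softmax (their logits are set to -Inf).
#'
#' @param Q,K,V Matrices of shape `T x d_k` (`K` and `V` share row count).
#' @param mask Optional 0/1 vector over key rows; 0 marks padding.
#' @return List with `output` (`T x d_k`) and `weights` (the attention
#'   matrix, rows summing to 1 over unmasked keys).
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  dk <- ncol(K)
  sc <- tcrossprod(Q, K) / sqrt(dk)
  if (!is.null(mask)) {
    if (all(mask == 0)) abort("all keys masked: attention undefined")
    sc[, mask == 0] <- -Inf
  }
  A <- row_softmax(sc)
  list(output = A %*% V, weights = A)
}

#' Multi-head self-attention
#'
#' Splits the model dimension into `h` heads, applies per-head projections
#' and scaled dot-product attention, concatenates the heads and projects with
#' the output matrix.
#'
#' @param X Input matrix `T x model_dim`.
#' @param params List with `Wq`, `Wk`, `Wv`, `Wo` (`model_dim x model_dim`)
#'   and `h` (number of heads; must divide `model_dim`).
#' @param mask Optional 0/1 key mask.
#' @return List with `output` (`T x model_dim`) and `weights` (list of
#'   per-head attention matrices).
#' @export
multi_head_attention <- function(X, params, mask = NULL) {
  d <- ncol(X); h <- params$h
  if (d %% h != 0) abort("number of heads must divide model_dim")
  dh <- d %/% h
  Q <- X %*% params$Wq; K <- X %*% params$Wk; V <- X %*% params$Wv
  out <- matrix(0, nrow(X), d)
  weights <- vector("list", h)
  for (i in seq_len(h)) {
    idx <- ((i - 1) * dh + 1):(i * dh)
    att <- scaled_dot_attention(Q[, idx, drop = FALSE], K[, idx, drop = FALSE],
                                V[, idx, drop = FALSE], mask)
    out[, idx] <- att$output
    weights[[i]] <- att$weights
  }
  list(output = out %*% params$Wo, weights = weights)
}
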