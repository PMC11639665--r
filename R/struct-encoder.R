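# GCN encoder over nucleotide graphs. Node features are projected to the
# hidden dimension, propagated through k graph-convolution layers over the
# symmetric degree-normalized adjacency (self-loops included), and pooled by
# a permutation-invariant readout into the structure embedding G.

gcn_init_params <- function(cfg) {
  par <- list(
    in_W = nn_init_mat(cfg$node_dim, cfg$gcn_hidden),
    in_b = numeric(cfg$gcn_hidden))
  dims <- c(rep(cfg$gcn_hidden, cfg$gcn_layers - 1), cfg$dim)
  d_in <- cfg$gcn_hidden
  for (l in seq_len(cfg$gcn_layers)) {
    par[[paste0("G", l, ".W")]] <- nn_init_mat(d_in, dims[l])
    par[[paste0("G", l, ".b")]] <- numeric(dims[l])
    d_in <- dims[l]
  }
  par
}

#' One graph-convolution layer
#'
#' Computes `sigma(A H W)` where `A` is the symmetric degree-normalized
#' adjacency with self-loops, so each node aggregates its neighbors and
#' itself weighted by `1/sqrt(deg_i deg_j)`.
#'
#' @param H `L x d_in` node state matrix.
#' @param A `L x L` normalized adjacency from [graph_adjacency()].
#' @param W `d_in x d_out` layer weight matrix.
#' @param bias Optional length-`d_out` bias (default zeros).
#' @param activation Activation function (default ReLU).
#' @return `L x d_out` updated node states.
#' @export
gcn_layer <- function(H, A, W, bias = NULL, activation = nn_relu) {
  if (ncol(H) != nrow(W)) abort("gcn_layer: dimension mismatch between H and W")
  if (nrow(H) != nrow(A)) abort("gcn_layer: adjacency/state size mismatch")
  Z <- A %*% H %*% W
  if (!is.null(bias)) Z <- add_bias(Z, bias)
  activation(Z)
}

#' Graph readout: pool node states to one vector
#'
#' Permutation-invariant pooling of the final node states into the
#' graph-level embedding. Mean pooling is the default; `sum` and `max` are
#' available.
#'
#' @param H `L x d` node state matrix, `L >= 1`.
#' @param type `"mean"` (default), `"sum"` or `"max"`.
#' @return Length-`d` numeric vector.
#' @export
gcn_readout <- function(H, type = c("mean", "sum", "max")) {
  type <- rlang::arg_match(type)
  if (nrow(H) == 0) abort("readout of an empty graph")
  switch(type,
         mean = colMeans(H),
         sum = colSums(H),
         max = apply(H, 2, max))
}

# Full GCN forward with caches for backprop.
gcn_forward <- function(par, cfg, graph, keep_cache = TRUE) {
  A <- graph$adjacency
  X <- graph$node_features
  pre0 <- add_bias(X %*% par$in_W, par$in_b)
  H <- nn_relu(pre0)
  Hs <- list(H)
  for (l in seq_len(cfg$gcn_layers)) {
    H <- gcn_layer(H, A, par[[paste0("G", l, ".W")]],
                   par[[paste0("G", l, ".b")]])
    Hs[[l + 1]] <- H
  }
  G <- gcn_readout(H, cfg$readout)
  list(G = G, Hs = if (keep_cache) Hs else NULL, A = A, X = X)
}

gcn_backward <- function(par, cfg, fwd, dG) {
  A <- fwd$A
  L <- nrow(A)
  H_last <- fwd$Hs[[cfg$gcn_layers + 1]]
  dH <- switch(cfg$readout,
               mean = matrix(dG / L, L, length(dG), byrow = TRUE),
               sum = matrix(dG, L, length(dG), byrow = TRUE),
               max = {
                 dm <- matrix(0, L, length(dG))
                 top <- apply(H_last, 2, which.max)
                 dm[cbind(top, seq_along(dG))] <- dG
                 dm
               })
  g <- list()
  for (l in rev(seq_len(cfg$gcn_layers))) {
    Hprev <- fwd$Hs[[l]]
    Hout <- fwd$Hs[[l + 1]]
    W <- par[[paste0("G", l, ".W")]]
    dpre <- dH
    dpre[Hout <= 0] <- 0
    P <- A %*% Hprev
    g[[paste0("G", l, ".W")]] <- crossprod(P, dpre)
    g[[paste0("G", l, ".b")]] <- colSums(dpre)
    dH <- A %*% tcrossprod(dpre, W)   # A is symmetric
  }
  dpre0 <- dH
  dpre0[fwd$Hs[[1]] <= 0] <- 0
  g$in_W <- crossprod(fwd$X, dpre0)
  g$in_b <- colSums(dpre0)
  g
}
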