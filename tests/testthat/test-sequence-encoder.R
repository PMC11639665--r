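test_that("scaled dot-product attention matches hand-computed softmax", {
  # zero queries -> uniform weights -> output is the mean of V rows
  Q <- matrix(0, 2, 2)
  K <- diag(2)
  V <- rbind(c(1, 0), c(0, 2))
  att <- scaled_dot_attention(Q, K, V)
  expect_equal(att$output, rbind(c(0.5, 1), c(0.5, 1)))
  expect_equal(rowSums(att$weights), c(1, 1))

  # query equal to one orthonormal key concentrates on its value row
  Qc <- matrix(c(10, 0), 1, 2)
  Kc <- 10 * diag(2)
  att2 <- scaled_dot_attention(Qc, Kc, V)
  w <- exp(c(100, 0) / sqrt(2)); w <- w / sum(w)
  expect_equal(as.numeric(att2$output), as.numeric(w %*% V))
  expect_gt(att2$weights[1, 1], 0.999)

  # permuting key/value rows together leaves the output unchanged
  set.seed(2); Qr <- matrix(rnorm(6), 3); Kr <- matrix(rnorm(6), 3)
  Vr <- matrix(rnorm(6), 3)
  perm <- c(3, 1, 2)
  expect_equal(scaled_dot_attention(Qr, Kr, Vr)$output,
               scaled_dot_attention(Qr, Kr[perm, ], Vr[perm, ])$output)

  expect_error(scaled_dot_attention(Qr, Kr, Vr, mask = c(0, 0, 0)),
               "all keys masked")
})

test_that("multi-head attention equals an explicit per-head computation", {
  set.seed(31)
  d <- 4; h <- 2; Tn <- 3
  X <- matrix(rnorm(Tn * d), Tn, d)
  params <- list(Wq = matrix(rnorm(d * d), d), Wk = matrix(rnorm(d * d), d),
                 Wv = matrix(rnorm(d * d), d), Wo = matrix(rnorm(d * d), d),
                 h = h)
  got <- multi_head_attention(X, params)

  # brute force: per-head projections, softmax, concat, output projection
  Q <- X %*% params$Wq; K <- X %*% params$Wk; V <- X %*% params$Wv
  heads <- lapply(1:h, function(i) {
    idx <- ((i - 1) * 2 + 1):(i * 2)
    sc <- Q[, idx] %*% t(K[, idx]) / sqrt(2)
    A <- exp(sc - apply(sc, 1, max)); A <- A / rowSums(A)
    A %*% V[, idx]
  })
  want <- do.call(cbind, heads) %*% params$Wo
  expect_equal(got$output, want, tolerance = 1e-12)

  # single head with zero output matrix gives zero
  params0 <- params; params0$h <- 1; params0$Wo <- params$Wo * 0
  expect_equal(multi_head_attention(X, params0)$output, matrix(0, Tn, d))
  expect_error(multi_head_attention(X, list(Wq = params$Wq, Wk = params$Wk,
                                            Wv = params$Wv, Wo = params$Wo,
                                            h = 3)), "divide")
})

test_that("attention rows sum to 1 at every head and layer", {
  cfg <- desk_tiny()
  set.seed(10)
  par <- rnafuse:::seq_init_params(cfg)
  v <- build_vocab(cfg$k)
  tok <- encode_tokens("ACGUACGUGGCC", v, 20)
  fwd <- rnafuse:::seq_forward(par, cfg, tok$ids, tok$attention_mask)
  for (l in seq_len(cfg$layers)) {
    for (A in fwd$caches[[l]]$A) {
      expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-5)
      expect_true(all(A[, tok$attention_mask == 0] == 0))
    }
  }
})

test_that("embeddings are padding-invariant and deterministic", {
  cfg <- desk_tiny()
  set.seed(11)
  par <- rnafuse:::seq_init_params(cfg)
  v <- build_vocab(cfg$k)
  s <- "ACGUACGUGG"
  emb <- function(max_len, pooling = "cls") {
    tok <- encode_tokens(s, v, max_len)
    fwd <- rnafuse:::seq_forward(par, cfg, tok$ids, tok$attention_mask,
                                 keep_cache = FALSE)
    rnafuse:::seq_pool(fwd$H, tok$attention_mask, pooling)
  }
  for (pooling in c("cls", "mean")) {
    e1 <- emb(14, pooling); e2 <- emb(20, pooling); e3 <- emb(24, pooling)
    expect_equal(e1, e2, tolerance = 1e-5)
    expect_equal(e1, e3, tolerance = 1e-5)
  }
  expect_identical(emb(20), emb(20))  # eval-mode determinism

  # different sequences give different embeddings at random init
  tok2 <- encode_tokens("GGGGGGGGGG", v, 20)
  fwd2 <- rnafuse:::seq_forward(par, cfg, tok2$ids, tok2$attention_mask,
                                keep_cache = FALSE)
  e_other <- rnafuse:::seq_pool(fwd2$H, tok2$attention_mask, "cls")
  expect_gt(max(abs(e_other - emb(20))), 1e-4)

  tok_bad <- encode_tokens(s, v, 14)
  tok_bad$ids[2] <- cfg$vocab_size
  expect_error(rnafuse:::seq_forward(par, cfg, tok_bad$ids,
                                     tok_bad$attention_mask), "vocabulary")
})

test_that("MLM loss has its closed forms and ignores unselected positions", {
  V <- 69
  logits <- matrix(0, 5, V)             # uniform
  labels <- c(3L, -1L, 10L, -1L, 0L)
  expect_equal(mlm_loss(logits, labels), log(V), tolerance = 1e-6)

  hot <- matrix(-1e6, 5, V)
  hot[cbind(1:5, c(4, 1, 11, 1, 1))] <- 1e6
  expect_lt(mlm_loss(hot, labels), 1e-6)

  noisy <- logits
  noisy[2, ] <- rnorm(V); noisy[4, ] <- rnorm(V)   # ignored rows
  expect_equal(mlm_loss(noisy, labels), mlm_loss(logits, labels))

  expect_error(mlm_loss(logits, rep(-1L, 5)), "no selected")
})
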