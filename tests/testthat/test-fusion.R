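test_that("contrastive loss has its closed forms", {
  expect_equal(contrastive_loss(matrix(rnorm(4), 1), matrix(rnorm(4), 1)), 0)

  for (N in c(2, 4, 8)) {
    S <- matrix(1, N, 3)
    expect_equal(contrastive_loss(S, S, delta = 0.37), log(N),
                 tolerance = 1e-6)
  }

  # orthonormal matched pairs at delta = 1: -log(e / (e + 1)) per direction
  S <- diag(2)
  expect_equal(contrastive_loss(S, S, delta = 1), log(1 + exp(-1)),
               tolerance = 1e-6)
  expect_equal(round(contrastive_loss(S, S, delta = 1), 4), 0.3133)

  expect_error(contrastive_loss(S, S, delta = 0), "delta")
  expect_error(contrastive_loss(rbind(c(0, 0), c(1, 0)), S), "zero-norm")
})

test_that("contrastive loss is symmetric and monotone in alignment", {
  set.seed(12)
  S <- matrix(rnorm(12), 4); G <- matrix(rnorm(12), 4)
  expect_equal(contrastive_loss(S, G), contrastive_loss(G, S))

  # strengthening the diagonal (G rows rotated toward matched S rows)
  # decreases the loss
  mix <- function(w) contrastive_loss(S, (1 - w) * G + w * S, delta = 0.5)
  vals <- vapply(c(0, 0.3, 0.6, 0.9), mix, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals >= 0))
})

test_that("shared projection applies per-modality linear + ReLU", {
  W <- rbind(c(1, -1), c(2, 0.5))
  S <- matrix(c(1, -2), 1)
  G <- matrix(c(0.5, 1), 1)
  z <- project_shared(S, G, W, W)
  expect_equal(z$z_seq, pmax(S %*% W, 0))
  expect_equal(z$z_struct, pmax(G %*% W, 0))
  # a negative pre-activation is clipped exactly
  expect_equal(as.numeric(z$z_seq), c(0, 0))  # (1-4, -1-1) -> both negative
  z0 <- project_shared(S, G, W * 0, W * 0)
  expect_equal(as.numeric(z0$z_seq), c(0, 0))
  expect_equal(z0$z_seq, z0$z_struct)
  expect_equal(project_shared(S, S, W, W)$z_seq,
               project_shared(S, S, W, W)$z_struct)
  expect_error(project_shared(S, G, W[, 1, drop = FALSE][1, , drop = FALSE], W),
               "mismatch")
})

test_that("attention fusion is a softmax-weighted convex combination", {
  t1 <- c(1, 0); t2 <- c(0, 1)
  f <- attention_fuse(list(t1, t1, t1), c(5, -3))
  expect_equal(f$alpha, rep(1 / 3, 3))
  expect_equal(f$fused, t1)

  # scores (0, ln 3) -> weights (0.25, 0.75)
  w <- c(log(3), 0)
  f2 <- attention_fuse(rbind(c(0, 1), c(1, 1)), w)
  expect_equal(f2$alpha, c(0.25, 0.75))
  expect_equal(f2$fused, 0.25 * c(0, 1) + 0.75 * c(1, 1))

  f3 <- attention_fuse(rbind(t1, t2), c(0, 0))
  expect_equal(f3$alpha, c(0.5, 0.5))

  # convex hull: weights nonnegative, sum 1, output inside coordinate bounds
  set.seed(4)
  toks <- matrix(rnorm(12), 4)
  f4 <- attention_fuse(toks, rnorm(3))
  expect_true(all(f4$alpha >= 0))
  expect_equal(sum(f4$alpha), 1)
  expect_true(all(f4$fused <= apply(toks, 2, max) + 1e-12))
  expect_true(all(f4$fused >= apply(toks, 2, min) - 1e-12))

  expect_error(attention_fuse(matrix(0, 0, 2), c(1, 1)), "at least one")
})

test_that("classification loss equals mean -log p(true class)", {
  expect_equal(classification_loss(matrix(1 / 7, 4, 7), c(1, 3, 5, 7)),
               log(7), tolerance = 1e-6)
  hot <- diag(3)
  expect_equal(classification_loss(hot, 1:3), 0)
  set.seed(6)
  P <- matrix(runif(15), 3); P <- P / rowSums(P)
  y <- c(2L, 5L, 1L)
  per <- vapply(1:3, function(i)
    classification_loss(P[i, , drop = FALSE], y[i]), numeric(1))
  expect_equal(classification_loss(P, y), mean(per))
  expect_error(classification_loss(P, c(2L, 6L, 1L)), "range")
  expect_error(classification_loss(P * 2, y), "sum to 1")
})

test_that("total loss is the constrained weighted sum", {
  expect_equal(total_loss(1.0, 0.5, alpha = 0.8, beta = 0.2), 0.9)
  expect_equal(total_loss(1.3, 9, alpha = 1, beta = 0), 1.3)
  expect_equal(total_loss(9, 1.3, alpha = 0, beta = 1), 1.3)
  expect_error(total_loss(1, 1, alpha = 0.7, beta = 0.4), "alpha")
  expect_error(rna_config("desk", alpha = 0.7, beta = 0.4), "alpha")
})

test_that("gradients flow to both encoders when 0 < alpha < 1", {
  cfg <- desk_tiny()
  set.seed(14)
  fpar <- rnafuse:::fusion_init_params(cfg)
  N <- 4
  S <- matrix(rnorm(N * cfg$dim), N); G <- matrix(rnorm(N * cfg$dim), N)
  ff <- rnafuse:::fusion_forward(fpar, cfg, S, G)
  fb <- rnafuse:::fusion_backward(fpar, cfg, ff, S, G, c(1L, 2L, 3L, 4L),
                                  loss_scale = cfg$alpha)
  cg <- rnafuse:::contrastive_loss_grad(S, G, cfg$delta)
  dS <- fb$dS + cfg$beta * cg$dS
  dG <- fb$dG + cfg$beta * cg$dG
  expect_gt(sqrt(sum(dS^2)), 0)
  expect_gt(sqrt(sum(dG^2)), 0)
})
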