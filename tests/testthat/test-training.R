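# Fast training-loop checks on a miniature configuration; the full desk-scale
# study conditions are exercised in test-acceptance.R.

tiny_bench <- function(seed = 0) generate_benchmark(n_per_family = 8, seed = seed)

test_that("a short MLM pre-training run reduces the loss", {
  cfg <- desk_tiny(pretrain_steps = 40L, batch_size = 8L, seed = 0L, k = 3L)
  m <- rna_pretrain(tiny_bench(), cfg)
  h <- m$pretrain_history
  expect_equal(nrow(h), 40)
  expect_lt(mean(tail(h$mlm_loss, 5)), h$mlm_loss[1])
  expect_error(rna_pretrain(tiny_bench()[0, ], cfg), "empty")
})

test_that("pre-training is bit-reproducible for a fixed seed", {
  cfg <- desk_tiny(pretrain_steps = 10L, batch_size = 4L, seed = 3L, k = 3L)
  m1 <- rna_pretrain(tiny_bench(), cfg)
  m2 <- rna_pretrain(tiny_bench(), cfg)
  expect_identical(m1$pretrain_history, m2$pretrain_history)
  expect_identical(m1$par, m2$par)
})

test_that("checkpoints reload to bit-identical eval-mode behavior", {
  cfg <- desk_tiny(pretrain_steps = 5L, batch_size = 4L, seed = 1L, k = 3L)
  bench <- tiny_bench()
  m <- rna_pretrain(bench, cfg)
  dir <- withr::local_tempdir()
  save_checkpoint(m, dir)
  m2 <- load_checkpoint(dir)
  expect_identical(m$par, m2$par)
  e1 <- embed_records(m, bench[1:5, ])
  e2 <- embed_records(m2, bench[1:5, ])
  expect_identical(e1$S, e2$S)
  expect_identical(e1$G, e2$G)
})

test_that("fine-tuning learns above chance and is reproducible", {
  bench <- tiny_bench()
  cfg <- desk_tiny(epochs = 6L, batch_size = 8L, seed = 0L, k = 3L,
                   lr = 3e-3)
  fit <- rna_finetune(bench, config = cfg)
  expect_equal(nrow(fit$history), 6)
  expect_gt(max(fit$history$val_acc), 1 / 7)

  fit2 <- rna_finetune(bench, config = cfg)
  expect_identical(fit$par, fit2$par)
  expect_identical(fit$history, fit2$history)
})

test_that("single-modality and zero-lr configurations behave as contracts say", {
  bench <- tiny_bench()
  # alpha = 1 trains without the contrastive term
  cfg <- desk_tiny(epochs = 2L, batch_size = 8L, seed = 0L, k = 3L,
                   alpha = 1, beta = 0)
  fit <- rna_finetune(bench, config = cfg)
  expect_true(all(fit$history$train_con == 0))

  # frozen model: zero learning rate leaves metrics identical across epochs
  cfg0 <- desk_tiny(epochs = 3L, batch_size = 8L, seed = 0L, k = 3L, lr = 0,
                    lr_gcn_mult = 1)
  fit0 <- rna_finetune(bench, config = cfg0)
  expect_equal(length(unique(fit0$history$val_acc)), 1)

  # a class missing from the training split warns but proceeds
  drop_fam <- bench[!(bench$family == "tRNA" & bench$split == "train"), ]
  expect_warning(
    rna_finetune(drop_fam, config = desk_tiny(epochs = 1L, batch_size = 8L,
                                              seed = 0L, k = 3L)),
    "absent")
  expect_error(rna_finetune(bench[bench$split != "train", ],
                            config = desk_tiny(k = 3L)), "training split")
})

test_that("prediction returns proper probability rows in fixed class order", {
  bench <- tiny_bench()
  cfg <- desk_tiny(epochs = 1L, batch_size = 8L, seed = 0L, k = 3L)
  fit <- rna_finetune(bench, config = cfg)
  te <- bench[bench$split == "test", ]
  p <- predict(fit, te)
  probs <- as.matrix(p[, paste0(".prob_", ncrna_families)])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(p)), tolerance = 1e-5)
  expect_equal(ncol(probs), 7)
  expect_true(all(p$.pred %in% ncrna_families))

  # duplicate record gives identical outputs
  dup <- te[c(1, 1), ]; dup$id <- c("a", "b")
  pd <- predict(fit, dup)
  expect_equal(as.numeric(pd[1, -1][, 1:7]), as.numeric(pd[2, -1][, 1:7]))
})

test_that("missing-structure policies drop or fall back as configured", {
  bench <- tiny_bench()
  bench$structure[bench$split == "test"][1:3] <- NA
  te <- bench[bench$split == "test", ]

  cfg <- desk_tiny(epochs = 1L, batch_size = 8L, seed = 0L, k = 3L)
  fit <- rna_finetune(bench[!is.na(bench$structure), ], config = cfg)

  expect_warning(p_drop <- predict(fit, te), "dropping 3")
  expect_equal(nrow(p_drop), nrow(te) - 3)

  fit$config$missing_structure <- "seq_fallback"
  p_fb <- predict(fit, te)
  expect_equal(nrow(p_fb), nrow(te))
  probs <- as.matrix(p_fb[, paste0(".prob_", ncrna_families)])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(te)), tolerance = 1e-5)
})

test_that("model summaries tidy, glance and plot", {
  bench <- tiny_bench()
  cfg <- desk_tiny(epochs = 2L, batch_size = 8L, seed = 0L, k = 3L)
  fit <- rna_finetune(bench, config = cfg)
  td <- tidy(fit)
  expect_true(all(c("epoch", "metric", "value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$epochs, 2L)
  expect_s3_class(autoplot(fit), "ggplot")
})
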