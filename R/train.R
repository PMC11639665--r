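# Training loops: self-supervised MLM pre-training of the sequence encoder,
# joint fine-tuning of both encoders plus the fusion head under the weighted
# total loss, and eval-mode prediction. All randomness flows from
# config$seed, making same-seed runs bit-reproducible on one machine.

prep_tokens <- function(manifest, vocab, max_len) {
  lapply(manifest$sequence, function(s) {
    # encode to natural length (capped): padding never changes results and
    # skipping it keeps desk-scale runs fast
    need <- min(nchar(s) - vocab$k + 1 + 2, max_len)
    encode_tokens(s, vocab, max(need, 3))
  })
}

prep_graphs <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    if (is.na(manifest$structure[i])) return(NULL)
    build_rna_graph(manifest$sequence[i],
                    parse_dot_bracket(manifest$structure[i]))
  })
}

#' Pre-train the sequence encoder with masked-language modelling
#'
#' Randomly masks k-mers (80% `[MASK]`, 10% random k-mer, 10% unchanged) and
#' trains the transformer to recover them. Only the sequence-encoder
#' parameters are updated; structures and labels are not used.
#'
#' @param manifest Manifest tibble; only `sequence` is used. Must be
#'   nonempty.
#' @param config An `rnafuse_config`; `pretrain_steps`, `pretrain_lr`,
#'   `mask_rate`, `batch_size` and `seed` drive the run.
#' @return An `rnafuse_model` with trained sequence encoder and a
#'   `pretrain_history` tibble (`step`, `mlm_loss`).
#' @export
rna_pretrain <- function(manifest, config = rna_config()) {
  if (nrow(manifest) == 0) abort("pre-training corpus is empty")
  set.seed(config$seed)
  model <- init_model(config)
  toks <- prep_tokens(manifest, model$vocab, config$max_len)
  n <- length(toks)
  state <- adam_init(model$par$seq)
  hist <- vector("list", config$pretrain_steps)
  for (step in seq_len(config$pretrain_steps)) {
    batch <- sample.int(n, min(config$batch_size, n))
    acc <- grad_zero(model$par$seq)
    loss_sum <- 0; n_sel <- 0
    for (i in batch) {
      mk <- mask_tokens(toks[[i]], model$vocab, config$mask_rate)
      if (mk$n_selected == 0) next
      fwd <- seq_forward(model$par$seq, config, mk$ids, mk$attention_mask)
      head <- mlm_head_fwd_bwd(model$par$seq, fwd$H, mk$labels)
      loss_sum <- loss_sum + head$loss_sum
      n_sel <- n_sel + head$n
      g <- seq_backward(model$par$seq, config, fwd, head$dH)
      g$mlm_W <- head$gW; g$mlm_b <- head$gb
      acc <- grad_add(acc, g)
    }
    if (n_sel == 0) abort("no masked positions in batch: MLM loss undefined")
    acc <- grad_scale(acc, 1 / n_sel)
    lr <- if (step <= config$pretrain_lr_switch) config$pretrain_lr else config$pretrain_lr2
    upd <- adam_step(model$par$seq, acc, state, lr, config$weight_decay)
    model$par$seq <- upd$params; state <- upd$state
    hist[[step]] <- tibble::tibble(step = step, mlm_loss = loss_sum / n_sel)
  }
  model$pretrain_history <- dplyr::bind_rows(hist)
  model
}

apply_structure_policy <- function(manifest, policy) {
  missing <- is.na(manifest$structure)
  if (policy == "drop" && any(missing)) {
    warn(sprintf("dropping %d record(s) without secondary structure",
                 sum(missing)))
    manifest <- manifest[!missing, ]
  }
  manifest
}

#' Fine-tune the full model for family classification
#'
#' Jointly optimizes the sequence encoder, structure encoder, fusion head and
#' classifier under `alpha * cross-entropy + beta * contrastive` (the
#' contrastive term needs both modalities and is dropped automatically for
#' single-modality ablations). The parameters achieving the best validation
#' accuracy are retained.
#'
#' @param manifest Labeled manifest with `train` and `val` split tags.
#' @param model Optional starting model (e.g. from [rna_pretrain()] or
#'   [load_checkpoint()]); a fresh one is initialized when `NULL`.
#' @param config An `rnafuse_config`.
#' @return The trained `rnafuse_model` with a `history` tibble
#'   (`epoch`, `train_loss`, `train_cls`, `train_con`, `val_acc`).
#' @export
rna_finetune <- function(manifest, model = NULL, config = rna_config()) {
  manifest <- as_ncrna_manifest(manifest)
  set.seed(config$seed)
  if (is.null(model)) {
    model <- init_model(config)
  } else {
    model$config <- config
  }
  cfg <- config
  manifest <- manifest[!is.na(manifest$family) & !is.na(manifest$split), ]
  if (cfg$modalities != "seq") {
    manifest <- apply_structure_policy(manifest, cfg$missing_structure)
  }
  train <- manifest[manifest$split == "train", ]
  val <- manifest[manifest$split == "val", ]
  if (nrow(train) == 0) abort("empty training split")
  if (nrow(val) == 0) abort("empty validation split")
  absent <- setdiff(model$classes, unique(train$family))
  if (length(absent) > 0) {
    warn(sprintf("class(es) absent from training split: %s",
                 paste(absent, collapse = ", ")))
  }
  toks <- prep_tokens(train, model$vocab, cfg$max_len)
  graphs <- prep_graphs(train)
  y <- as.integer(factor(train$family, levels = model$classes))
  use_con <- cfg$modalities == "both" && cfg$beta > 0
  flat <- pack_params(model$par)
  state <- adam_init(flat)
  # the GCN is far shallower than the transformer and trains best with a
  # larger step size; per-module learning rates are standard practice
  lr_vec <- stats::setNames(
    ifelse(startsWith(names(flat), "gcn/"),
           cfg$lr * (cfg$lr_gcn_mult %||% 1), cfg$lr),
    names(flat))
  best <- list(acc = -Inf, par = model$par)
  hist <- vector("list", cfg$epochs)
  n <- nrow(train)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- c(total = 0, cls = 0, con = 0); n_batch <- 0
    for (bs in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      N <- length(bs)
      S <- matrix(0, N, cfg$dim); G <- matrix(0, N, cfg$dim)
      seq_fwds <- vector("list", N); gcn_fwds <- vector("list", N)
      for (j in seq_len(N)) {
        i <- bs[j]
        sf <- seq_forward(model$par$seq, cfg, toks[[i]]$ids,
                          toks[[i]]$attention_mask)
        seq_fwds[[j]] <- sf
        S[j, ] <- seq_pool(sf$H, toks[[i]]$attention_mask, cfg$pooling)
        if (!is.null(graphs[[i]]) && cfg$modalities != "seq") {
          gf <- gcn_forward(model$par$gcn, cfg, graphs[[i]])
          gcn_fwds[[j]] <- gf
          G[j, ] <- gf$G
        }
      }
      ff <- fusion_forward(model$par$fus, cfg, S, G)
      l_cls <- mean(-log(pmax(ff$probs[cbind(seq_len(N), y[bs])], 1e-12)))
      fb <- fusion_backward(model$par$fus, cfg, ff, S, G, y[bs],
                            loss_scale = cfg$alpha)
      dS <- fb$dS; dG <- fb$dG
      l_con <- 0
      # contrastive term over records that actually have both modalities
      ok <- which(!vapply(gcn_fwds, is.null, logical(1)))
      if (use_con && length(ok) > 1) {
        cg <- contrastive_loss_grad(S[ok, , drop = FALSE],
                                    G[ok, , drop = FALSE], cfg$delta)
        l_con <- cg$loss
        dS[ok, ] <- dS[ok, , drop = FALSE] + cfg$beta * cg$dS
        dG[ok, ] <- dG[ok, , drop = FALSE] + cfg$beta * cg$dG
      }
      acc_seq <- grad_zero(model$par$seq)
      acc_gcn <- grad_zero(model$par$gcn)
      for (j in seq_len(N)) {
        i <- bs[j]
        dH <- seq_pool_bwd(dS[j, ], length(toks[[i]]$ids),
                           toks[[i]]$attention_mask, cfg$pooling)
        gs <- seq_backward(model$par$seq, cfg, seq_fwds[[j]], dH)
        acc_seq <- grad_add(acc_seq, gs)
        if (!is.null(gcn_fwds[[j]])) {
          acc_gcn <- grad_add(acc_gcn,
                              gcn_backward(model$par$gcn, cfg, gcn_fwds[[j]],
                                           dG[j, ]))
        }
      }
      grads <- pack_params(list(seq = acc_seq, gcn = acc_gcn, fus = fb$grads))
      flat <- pack_params(model$par)
      upd <- adam_step(flat, grads, state, lr_vec, cfg$weight_decay)
      model$par <- unpack_params(upd$params)
      state <- upd$state
      ep_loss <- ep_loss +
        c(cfg$alpha * l_cls + cfg$beta * l_con, l_cls, l_con)
      n_batch <- n_batch + 1
    }
    preds <- predict(model, val)
    val_acc <- mean(preds$.pred == val$family[match(preds$id, val$id)])
    # ">=" keeps the most-trained parameters among equal validation scores
    if (val_acc >= best$acc) best <- list(acc = val_acc, par = model$par)
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch,
      train_loss = ep_loss[["total"]] / n_batch,
      train_cls = ep_loss[["cls"]] / n_batch,
      train_con = ep_loss[["con"]] / n_batch,
      val_acc = val_acc)
  }
  model$par <- best$par
  model$history <- dplyr::bind_rows(hist)
  model
}

#' Predict family probabilities for records
#'
#' Eval-mode forward pass: probabilities per family (columns in the fixed
#' [ncrna_families] order) plus the argmax label. Records without structure
#' are skipped with a warning under the `"drop"` policy, or encoded with a
#' zero structure embedding under `"seq_fallback"`.
#'
#' @param object A trained `rnafuse_model`.
#' @param newdata Manifest tibble of records to classify.
#' @param ... Unused.
#' @return A tibble with `id`, one `.prob_<family>` column per class, and
#'   `.pred` (probability rows sum to 1).
#' @export
predict.rnafuse_model <- function(object, newdata, ...) {
  cfg <- object$config
  manifest <- tibble::as_tibble(newdata)
  if (cfg$modalities != "seq") {
    manifest <- apply_structure_policy(manifest, cfg$missing_structure)
  }
  if (nrow(manifest) == 0) {
    abort("no records left to predict (all dropped for missing structure?)")
  }
  emb <- embed_records(object, manifest)
  ff <- fusion_forward(object$par$fus, cfg, emb$S, emb$G)
  probs <- ff$probs
  colnames(probs) <- paste0(".prob_", object$classes)
  out <- tibble::as_tibble(probs)
  out$id <- manifest$id
  out$.pred <- object$classes[max.col(probs, ties.method = "first")]
  dplyr::relocate(out, "id")
}
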