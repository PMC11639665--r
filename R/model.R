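# Model container and checkpointing. A model bundles the configuration, the
# k-mer vocabulary and three flat parameter lists (sequence encoder, GCN,
# fusion head). Checkpoints are a directory {config.json, vocab.json,
# weights.rds}; reloading reproduces eval-mode embeddings bit-exactly.

#' Initialize a fresh model
#'
#' All parameters are drawn from the current RNG state: call `set.seed()`
#' first (or rely on [rna_pretrain()]/[rna_finetune()], which seed from
#' `config$seed`).
#'
#' @param config An `rnafuse_config`.
#' @return An object of class `rnafuse_model`.
#' @export
init_model <- function(config = rna_config()) {
  vocab <- build_vocab(config$k)
  structure(list(
    config = config,
    vocab = vocab,
    classes = ncrna_families,
    par = list(seq = seq_init_params(config),
               gcn = gcn_init_params(config),
               fus = fusion_init_params(config))),
    class = "rnafuse_model")
}

#' @export
print.rnafuse_model <- function(x, ...) {
  np <- sum(vapply(unlist(x$par, recursive = FALSE), length, numeric(1)))
  cat(sprintf("<rnafuse_model: %s preset, %d parameters, %d classes%s>\n",
              x$config$preset, np, length(x$classes),
              if (!is.null(x$history)) ", fine-tuned" else ""))
  invisible(x)
}

# Flatten the nested parameter list for the optimizer and back.
pack_params <- function(par) {
  out <- list()
  for (grp in names(par)) {
    sub <- par[[grp]]
    names(sub) <- paste0(grp, "/", names(sub))
    out <- c(out, sub)
  }
  out
}

unpack_params <- function(flat) {
  grp <- sub("/.*$", "", names(flat))
  out <- list()
  for (g in unique(grp)) {
    sub <- flat[grp == g]
    names(sub) <- sub("^[^/]*/", "", names(sub))
    out[[g]] <- sub
  }
  out
}

#' Embed records with both encoders
#'
#' Runs the sequence encoder and the structure encoder in eval mode and
#' returns the per-molecule embeddings (the inputs to contrastive alignment
#' and fusion). Useful for downstream visualisation, e.g. t-SNE/UMAP export.
#'
#' @param model An `rnafuse_model`.
#' @param manifest Manifest tibble.
#' @return List with `id`, `S` (`N x d` sequence embeddings) and `G`
#'   (`N x d` structure embeddings; zero rows where structure is absent).
#' @export
embed_records <- function(model, manifest) {
  cfg <- model$config
  n <- nrow(manifest)
  S <- matrix(0, n, cfg$dim); G <- matrix(0, n, cfg$dim)
  for (i in seq_len(n)) {
    tok <- encode_tokens(manifest$sequence[i], model$vocab, cfg$max_len)
    fwd <- seq_forward(model$par$seq, cfg, tok$ids, tok$attention_mask,
                       keep_cache = FALSE)
    S[i, ] <- seq_pool(fwd$H, tok$attention_mask, cfg$pooling)
    if (!is.na(manifest$structure[i])) {
      graph <- build_rna_graph(manifest$sequence[i],
                               parse_dot_bracket(manifest$structure[i]))
      G[i, ] <- gcn_forward(model$par$gcn, cfg, graph, keep_cache = FALSE)$G
    }
  }
  list(id = manifest$id, S = S, G = G)
}

#' Save a model checkpoint
#'
#' Writes `config.json`, `vocab.json` (token to id map) and `weights.rds`
#' into `dir`.
#'
#' @param model An `rnafuse_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(model$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(model$vocab$ids), file.path(dir, "vocab.json"),
                       auto_unbox = TRUE)
  saveRDS(list(par = model$par, classes = model$classes,
               history = model$history,
               pretrain_history = model$pretrain_history),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' Load a model checkpoint
#' @param dir Checkpoint directory written by [save_checkpoint()].
#' @return The restored `rnafuse_model`.
#' @export
load_checkpoint <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg$pretrain_lr_switch <- as.numeric(cfg$pretrain_lr_switch)  # Inf round trip
  if (is.na(cfg$pretrain_lr_switch)) cfg$pretrain_lr_switch <- Inf
  cfg <- validate_config(cfg)
  blob <- readRDS(file.path(dir, "weights.rds"))
  model <- structure(list(
    config = cfg, vocab = build_vocab(cfg$k), classes = blob$classes,
    par = blob$par), class = "rnafuse_model")
  model$history <- blob$history
  model$pretrain_history <- blob$pretrain_history
  model
}
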