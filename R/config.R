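# Run configuration. Two presets: "paper" is the full-scale training
# protocol of the original method (12-layer, d = 768, max_len 512, Adam lr
# 2e-5, weight decay 1e-4, 10 epochs, 200k pre-training steps with a
# 1e-4 -> 1e-6 schedule, 15% masking, alpha = 0.8); "desk" shrinks the
# architecture and step counts so the full pipeline runs in minutes on one
# CPU while keeping every objective and ratio identical.

#' Build a run configuration
#'
#' @param preset `"desk"` (default; 2 transformer layers, d = 64, max_len
#'   128) or `"paper"` (12 layers, d = 768, max_len 512).
#' @param ... Named overrides for any configuration field: `k`, `max_len`,
#'   `dim`, `heads`, `layers`, `ffn`, `gcn_layers`, `gcn_hidden`, `readout`,
#'   `dz`, `pooling`, `delta` (contrastive temperature), `alpha`, `beta`
#'   (loss weights, must sum to 1), `fusion_mode`
#'   (`"attention"`/`"sum"`/`"concat"`), `modalities`
#'   (`"both"`/`"seq"`/`"struct"`), `mask_rate`, `lr`, `lr_gcn_mult`
#'   (learning-rate multiplier for the GCN parameters), `pretrain_lr`,
#'   `pretrain_lr2`, `pretrain_lr_switch`, `weight_decay`, `epochs`,
#'   `pretrain_steps`, `batch_size`, `seed`, `missing_structure`
#'   (`"drop"`/`"seq_fallback"`).
#' @return A validated list of class `rnafuse_config`.
#' @export
rna_config <- function(preset = c("desk", "paper"), ...) {
  preset <- rlang::arg_match(preset)
  cfg <- list(
    preset = preset,
    k = 3L, n_classes = 7L, node_dim = NODE_FEATURE_DIM,
    readout = "mean",
    delta = 0.1, alpha = 0.8, beta = 0.2,
    fusion_mode = "attention", modalities = "both",
    mask_rate = 0.15, weight_decay = 1e-4,
    epochs = 10L, seed = 0L,
    missing_structure = "drop")
  if (preset == "desk") {
    # mean pooling: at this scale a randomly initialized CLS channel has not
    # yet learned to aggregate, while the token mean carries signal from step 1
    cfg <- utils::modifyList(cfg, list(
      max_len = 128L, dim = 64L, heads = 4L, layers = 2L, ffn = 128L,
      gcn_layers = 2L, gcn_hidden = 64L, dz = 64L, pooling = "mean",
      lr = 1e-3, lr_gcn_mult = 10, batch_size = 8L,
      pretrain_lr = 1e-3, pretrain_lr2 = 1e-3,
      pretrain_lr_switch = Inf, pretrain_steps = 200L))
  } else {
    cfg <- utils::modifyList(cfg, list(
      max_len = 512L, dim = 768L, heads = 12L, layers = 12L, ffn = 3072L,
      gcn_layers = 3L, gcn_hidden = 768L, dz = 768L, pooling = "cls",
      lr = 2e-5, lr_gcn_mult = 1, batch_size = 16L,
      pretrain_lr = 1e-4, pretrain_lr2 = 1e-6,
      pretrain_lr_switch = 1e5, pretrain_steps = 2e5))
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg)))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if ("alpha" %in% names(dots) && !("beta" %in% names(dots))) {
    dots$beta <- 1 - dots$alpha
  }
  cfg <- utils::modifyList(cfg, dots)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  check_alpha_beta(cfg$alpha, cfg$beta)
  if (cfg$delta <= 0) abort("temperature delta must be > 0")
  if (cfg$dim %% cfg$heads != 0) abort("heads must divide dim")
  if (cfg$k < 1 || cfg$k > 8) abort("k must be in [1, 8]")
  if (!cfg$fusion_mode %in% c("attention", "sum", "concat")) {
    abort("fusion_mode must be one of attention/sum/concat")
  }
  if (!cfg$modalities %in% c("both", "seq", "struct")) {
    abort("modalities must be one of both/seq/struct")
  }
  if (!cfg$missing_structure %in% c("drop", "seq_fallback")) {
    abort("missing_structure must be 'drop' or 'seq_fallback'")
  }
  if (!cfg$readout %in% c("mean", "sum", "max")) {
    abort("readout must be one of mean/sum/max")
  }
  if (!cfg$pooling %in% c("cls", "mean")) {
    abort("pooling must be 'cls' or 'mean'")
  }
  cfg$vocab_size <- 4L^cfg$k + 5L
  structure(cfg, class = "rnafuse_config")
}

#' @export
print.rnafuse_config <- function(x, ...) {
  cat(sprintf(
    "<rnafuse_config: preset=%s k=%d dim=%d layers=%d max_len=%d alpha=%.2f beta=%.2f delta=%.2g fusion=%s modalities=%s>\n",
    x$preset, x$k, x$dim, x$layers, x$max_len, x$alpha, x$beta, x$delta,
    x$fusion_mode, x$modalities))
  invisible(x)
}
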