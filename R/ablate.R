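# Ablation driver: trains three configurations on one benchmark —
# sequence-only, structure-only, and the fused model — and reports test-set
# metrics side by side, mirroring the seq / struct_graph / combined
# comparison the full framework is motivated by.

#' Run the three-way modality ablation on a benchmark
#'
#' Fine-tunes (from random initialization, or from `model` if given) a
#' sequence-only model, a structure-only model and the fused model on the
#' benchmark's train/val splits, then evaluates each on the test split.
#' Single-modality runs drop the contrastive term (it needs both
#' modalities), i.e. run with `alpha = 1`.
#'
#' @param benchmark A labeled, split manifest (see [generate_benchmark()]).
#' @param config Base `rnafuse_config`; `modalities`, `alpha`, `beta` are
#'   overridden per arm.
#' @param model Optional pre-trained starting model shared by all arms.
#' @return A tibble with one row per arm (`seq`, `struct`, `fused`) and
#'   columns `acc`, `f1`, `mcc`, `precision`, `recall`.
#' @export
run_ablation <- function(benchmark, config = rna_config(), model = NULL) {
  test <- benchmark[benchmark$split == "test", ]
  arms <- list(
    seq = list(modalities = "seq", alpha = 1, beta = 0),
    struct = list(modalities = "struct", alpha = 1, beta = 0),
    fused = list(modalities = "both", alpha = config$alpha,
                 beta = config$beta))
  out <- lapply(names(arms), function(nm) {
    cfg <- validate_config(utils::modifyList(unclass(config), arms[[nm]]))
    fit <- rna_finetune(benchmark, model = model, config = cfg)
    preds <- predict(fit, test)
    ev <- rna_evaluate(test$family[match(preds$id, test$id)], preds$.pred)
    dplyr::bind_cols(tibble::tibble(model = nm), glance(ev))
  })
  dplyr::bind_rows(out)
}
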