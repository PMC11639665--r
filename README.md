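# rnafuse

Multi-modal classification of non-coding RNAs into families by fusing a
masked-language-model transformer over the primary sequence with a graph
convolutional network over the secondary structure.

## The problem

Non-coding RNAs in the same family (tRNA, snoRNA, Y RNA, ...) share
function, so family assignment is a basic annotation step. A molecule
carries two complementary information channels — its sequence and its
base-pairing pattern (dot-bracket notation) — and classifiers that use only
one discard the other. `rnafuse` is for computational RNA biologists who
want a tested, CPU-scale implementation of the full multi-modal recipe:

* **Sequence encoder** — overlapping k-mers (default k = 3) feed a
  BERT-style transformer, `Attention(Q,K,V) = softmax(QKᵀ/√d_k)V`,
  pre-trained by masked-language modelling (15% of k-mers masked,
  80/10/10 corruption) and pooled to a per-molecule embedding *S*.
* **Structure encoder** — each molecule becomes a nucleotide graph
  (15-dim node features, backbone plus base-pair edges, pseudoknots
  included); a GCN with symmetric degree-normalized adjacency
  `H' = σ(Â H W)` and mean readout yields the structure embedding *G*.
* **Alignment and fusion** — a symmetric InfoNCE loss with temperature δ
  pulls matched (*S*, *G*) pairs together; both modalities are projected
  into a shared space and combined by softmax attention; an MLP classifies
  into seven families (rRNA, Y_RNA, snRNA, snoRNA, SRP_RNA, tRNA,
  pre_miRNA). Training minimizes
  `L = α·L_classification + β·L_contrastive` with `α + β = 1`
  (default α = 0.8).

All encoders, losses and backpropagation are implemented in base R matrix
code and verified by finite-difference gradient tests. A synthetic-data
module generates labeled families with controllable sequence signal
(composition, planted motifs) and structure signal (designed hairpin /
cloverleaf / pseudoknot templates), so the whole pipeline — including the
sequence-only / structure-only / fused ablation — runs at desk scale
without downloads.

## Worked example

```r
library(rnafuse)

bench <- generate_benchmark(n_per_family = 20, seed = 0)  # 7 families, 2:1:1 split
cfg   <- rna_config("desk", seed = 0L)

pre <- rna_pretrain(bench, cfg)          # 200 MLM steps on the sequences
fit <- rna_finetune(bench, model = pre, config = cfg)

test  <- dplyr::filter(bench, split == "test")
preds <- predict(fit, test)
rna_evaluate(test$family, preds$.pred)
```

```
<rnafuse_eval: n=35  ACC=0.7429  precision=0.8111  recall=0.7429  F1=0.7290  MCC=0.7116>
```

The MLM loss falls from 4.708 to 3.441 over pre-training (uniform baseline
ln 69 ≈ 4.234), and the fine-tuned fused model classifies 26/35 held-out
records correctly; `glance()` returns the one-row metric summary
(accuracy, macro precision/recall/F1 and the multiclass Matthews
correlation computed from the confusion matrix), `tidy()` the per-class
breakdown, and `autoplot()` draws the confusion heatmap:

```r
glance(rna_evaluate(test$family, preds$.pred))
#> # A tibble: 1 × 6
#>     acc precision recall    f1   mcc     n
#> 1 0.743     0.811  0.743 0.729 0.712    35
```

The three-arm modality ablation (sequence-only, structure-only, fused)
is one call — `run_ablation(bench, cfg, model = pre)` — and a command-line
interface wraps the same functions
(`inst/cli/rnafuse simulate|pretrain|finetune|predict|evaluate|ablate|graph-export`).

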