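# Synthetic ncRNA family generator. Families are defined by a designed
# (template-based, not folded) secondary structure plus an optional planted
# sequence motif; stems are Watson-Crick complementary up to a mutation rate.
# This gives exact ground truth for both modalities and lets the sequence
# signal and the structure signal be switched on independently, which is what
# the ablation benchmarks need.

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Define a synthetic family
#'
#' @param name Family label (one of [ncrna_families] for the stock
#'   benchmarks, but any label accepted here).
#' @param length_range Length-2 integer vector `(min, max)` of total
#'   sequence length in nucleotides.
#' @param template Structure template list with `type` one of `"hairpin"`
#'   (`stem`, `loop`), `"double_hairpin"` (`stem`, `loop`, `spacer`, and
#'   optionally `stem2`, `loop2`), `"pseudoknot"` (`stem`, `pk_stem`, gaps
#'   `gap1`-`gap3`; an H-type knot whose second stem crosses the first) or
#'   `"unpaired"`.
#' @param motif Optional motif string planted in an unpaired region.
#' @param motif_prob Probability the motif is planted in a record.
#' @param mutation_rate Per-position probability of substituting a random
#'   base after template instantiation (structure string kept fixed,
#'   mimicking within-family sequence variation).
#' @param gc_content Target GC fraction of the family's sequences (real
#'   ncRNA families differ markedly in composition). Bases are drawn with
#'   `P(G) = P(C) = gc/2`, `P(A) = P(U) = (1-gc)/2`; Watson-Crick stem
#'   complementarity preserves the GC fraction.
#' @param flank `"random"` (default) or `"balanced"` split of the leftover
#'   unpaired length around the template core; `"balanced"` makes the
#'   structure string deterministic given the total length.
#' @return A `family_spec` list.
#' @export
family_spec <- function(name, length_range, template = list(type = "unpaired"),
                        motif = NULL, motif_prob = 0.9, mutation_rate = 0.05,
                        gc_content = 0.5, flank = c("random", "balanced")) {
  flank <- rlang::arg_match(flank)
  spec <- list(name = name, length_range = as.integer(length_range),
               template = template, motif = motif, motif_prob = motif_prob,
               mutation_rate = mutation_rate, gc_content = gc_content,
               flank = flank)
  mn <- template_min_len(template)
  if (spec$length_range[1] < mn) {
    abort(sprintf("family '%s': length_range minimum %d cannot host template (needs >= %d)",
                  name, spec$length_range[1], mn))
  }
  structure(spec, class = "family_spec")
}

template_min_len <- function(tpl) {
  switch(tpl$type,
    unpaired = 1L,
    hairpin = 2L * tpl$stem + tpl$loop,
    double_hairpin = {
      s2 <- tpl$stem2 %||% tpl$stem; l2 <- tpl$loop2 %||% tpl$loop
      2L * tpl$stem + tpl$loop + tpl$spacer + 2L * s2 + l2
    },
    pseudoknot = {
      g <- c(tpl$gap1 %||% 3L, tpl$gap2 %||% 3L, tpl$gap3 %||% 3L)
      2L * tpl$stem + 2L * tpl$pk_stem + sum(g)
    },
    abort(sprintf("unknown template type '%s'", tpl$type)))
}

# Instantiate the dot-bracket string of one record.
instantiate_structure <- function(tpl, L, flank) {
  core <- switch(tpl$type,
    unpaired = "",
    hairpin = paste0(strrep("(", tpl$stem), strrep(".", tpl$loop),
                     strrep(")", tpl$stem)),
    double_hairpin = {
      s2 <- tpl$stem2 %||% tpl$stem; l2 <- tpl$loop2 %||% tpl$loop
      paste0(strrep("(", tpl$stem), strrep(".", tpl$loop),
             strrep(")", tpl$stem), strrep(".", tpl$spacer),
             strrep("(", s2), strrep(".", l2), strrep(")", s2))
    },
    pseudoknot = {
      g1 <- tpl$gap1 %||% 3L; g2 <- tpl$gap2 %||% 3L; g3 <- tpl$gap3 %||% 3L
      paste0(strrep("(", tpl$stem), strrep(".", g1),
             strrep("[", tpl$pk_stem), strrep(".", g2),
             strrep(")", tpl$stem), strrep(".", g3),
             strrep("]", tpl$pk_stem))
    })
  extra <- L - nchar(core)
  left <- if (flank == "balanced") extra %/% 2L else sample.int(extra + 1L, 1L) - 1L
  paste0(strrep(".", left), core, strrep(".", extra - left))
}

#' Generate one synthetic record
#'
#' @param spec A [family_spec()].
#' @param id Record identifier.
#' @return One-row manifest tibble (split tag left `NA`).
#' @export
generate_record <- function(spec, id = spec$name) {
  L <- if (spec$length_range[1] == spec$length_range[2]) spec$length_range[1]
       else sample(spec$length_range[1]:spec$length_range[2], 1)
  db <- instantiate_structure(spec$template, L, spec$flank)
  pairs <- parse_dot_bracket(db)
  gc <- spec$gc_content %||% 0.5
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  base <- sample(NT_LEVELS, L, replace = TRUE, prob = probs)
  if (nrow(pairs) > 0) {
    base[pairs$pos3] <- RNA_COMPLEMENT[base[pairs$pos5]]
  }
  mut <- runif(L) < spec$mutation_rate
  if (any(mut)) base[mut] <- sample(NT_LEVELS, sum(mut), replace = TRUE, prob = probs)
  if (!is.null(spec$motif) && runif(1) < spec$motif_prob) {
    mlen <- nchar(spec$motif)
    runs <- rle(strsplit(db, "")[[1]] == ".")
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    fit <- which(runs$values & runs$lengths >= mlen)
    if (length(fit) > 0) {
      r <- fit[sample.int(length(fit), 1)]
      at <- starts[r] + sample.int(runs$lengths[r] - mlen + 1, 1) - 1
      base[at:(at + mlen - 1)] <- strsplit(spec$motif, "")[[1]]
    }
  }
  tibble::tibble(id = id, sequence = paste(base, collapse = ""),
                 structure = db, family = spec$name, split = NA_character_)
}

#' Stock seven-family specifications
#'
#' One spec per family in [ncrna_families], each with a distinct planted
#' motif, a distinct base composition (GC fractions spread over 0.30-0.70,
#' as real families differ in composition) and a distinct designed structure
#' (hairpins of varying geometry, a cloverleaf-like double hairpin for
#' tRNA/snRNA, an H-type pseudoknot for SRP_RNA). Lengths span roughly
#' 50-200 nt. Both the sequence signal and the structure signal are
#' informative, emulating a family benchmark where either modality can
#' classify and fusion should do at least as well.
#'
#' @param motif_prob,mutation_rate Noise parameters shared by all families.
#' @return Named list of `family_spec`s.
#' @export
default_family_specs <- function(motif_prob = 0.9, mutation_rate = 0.05) {
  fs <- function(...) family_spec(..., motif_prob = motif_prob,
                                  mutation_rate = mutation_rate)
  list(
    rRNA = fs("rRNA", c(100, 160), list(type = "hairpin", stem = 10, loop = 8),
              motif = "CCGAUGA", gc_content = 0.75),
    Y_RNA = fs("Y_RNA", c(90, 130), list(type = "hairpin", stem = 12, loop = 10),
               motif = "GUAGUGA", gc_content = 0.30),
    snRNA = fs("snRNA", c(90, 150),
               list(type = "double_hairpin", stem = 6, loop = 8, spacer = 10),
               motif = "AUUUUUG", gc_content = 0.20),
    snoRNA = fs("snoRNA", c(60, 100), list(type = "hairpin", stem = 5, loop = 14),
                motif = "AUGAUGA", gc_content = 0.50),
    SRP_RNA = fs("SRP_RNA", c(100, 150),
                 list(type = "pseudoknot", stem = 8, pk_stem = 4,
                      gap1 = 3, gap2 = 4, gap3 = 6),
                 motif = "GCCAGGU", gc_content = 0.80),
    tRNA = fs("tRNA", c(60, 90),
              list(type = "double_hairpin", stem = 5, loop = 7, spacer = 8),
              motif = "UUCGAAU", gc_content = 0.60),
    pre_miRNA = fs("pre_miRNA", c(50, 90),
                   list(type = "hairpin", stem = 18, loop = 10),
                   motif = "GGCUCAG", gc_content = 0.40))
}

#' Generate a labeled, split benchmark
#'
#' `n_per_family` records per family with a label-stratified
#' train/validation/test split (default ratio 2:1:1). Fully deterministic
#' given `seed`.
#'
#' @param families List of [family_spec()]s; default [default_family_specs()].
#' @param n_per_family Records per family (at least 4 so every split is
#'   nonempty).
#' @param split_ratio Length-3 ratio for train/val/test.
#' @param seed Integer seed.
#' @return A manifest tibble of `length(families) * n_per_family` records.
#' @export
generate_benchmark <- function(families = default_family_specs(),
                               n_per_family = 20, split_ratio = c(2, 1, 1),
                               seed = 0) {
  if (n_per_family < 4) abort("n_per_family must be at least 4 to fill a 2:1:1 split")
  set.seed(seed)
  rows <- list()
  for (spec in families) {
    recs <- dplyr::bind_rows(lapply(seq_len(n_per_family), function(i) {
      generate_record(spec, id = sprintf("%s_%04d", spec$name, i))
    }))
    w <- split_ratio / sum(split_ratio)
    n_tr <- floor(n_per_family * w[1])
    n_va <- floor(n_per_family * w[2])
    tags <- c(rep("train", n_tr), rep("val", n_va),
              rep("test", n_per_family - n_tr - n_va))
    recs$split <- tags[sample.int(n_per_family)]
    rows[[spec$name]] <- recs
  }
  as_ncrna_manifest(dplyr::bind_rows(rows))
}

#' Ablation benchmark pair: structure-only and sequence-only signal
#'
#' Benchmark A ("structure_only"): all families share the same length range
#' and base composition (uniform, no motifs) but carry distinct structure
#' templates, so class signal is reachable only through the structure graphs.
#' Benchmark B ("sequence_only"): all families share one fixed-length hairpin
#' template with balanced flanks (every structure string is identical) but
#' differ in base composition (GC fractions 0.20-0.80) and planted motifs,
#' so class signal is reachable only through the sequence.
#'
#' @param seed Integer seed.
#' @param n_per_family Records per family in each benchmark.
#' @return List with manifests `structure_only` and `sequence_only`.
#' @export
make_ablation_pair <- function(seed = 0, n_per_family = 20) {
  rng <- c(100L, 140L)
  struct_specs <- list(
    family_spec("rRNA", rng, list(type = "hairpin", stem = 6, loop = 20),
                mutation_rate = 0.05),
    family_spec("Y_RNA", rng, list(type = "hairpin", stem = 14, loop = 6),
                mutation_rate = 0.05),
    family_spec("snRNA", rng,
                list(type = "double_hairpin", stem = 6, loop = 6, spacer = 8),
                mutation_rate = 0.05),
    family_spec("snoRNA", rng,
                list(type = "double_hairpin", stem = 10, loop = 4, spacer = 4),
                mutation_rate = 0.05),
    family_spec("SRP_RNA", rng,
                list(type = "pseudoknot", stem = 8, pk_stem = 5),
                mutation_rate = 0.05),
    family_spec("tRNA", rng, list(type = "hairpin", stem = 20, loop = 8),
                mutation_rate = 0.05),
    family_spec("pre_miRNA", rng, list(type = "unpaired"),
                mutation_rate = 0.05))
  seq_tpl <- list(type = "hairpin", stem = 8, loop = 12)
  motifs <- c(rRNA = "CCGAUGA", Y_RNA = "GUAGUGA", snRNA = "AUUUUUG",
              snoRNA = "AUGAUGA", SRP_RNA = "GCCAGGU", tRNA = "UUCGAAU",
              pre_miRNA = "GGCUCAG")
  gcs <- stats::setNames(seq(0.2, 0.8, by = 0.1), names(motifs))
  seq_specs <- lapply(names(motifs), function(nm) {
    family_spec(nm, c(120L, 120L), seq_tpl, motif = motifs[[nm]],
                motif_prob = 1, mutation_rate = 0.05,
                gc_content = gcs[[nm]], flank = "balanced")
  })
  list(
    structure_only = generate_benchmark(struct_specs, n_per_family,
                                        seed = seed),
    sequence_only = generate_benchmark(seq_specs, n_per_family,
                                       seed = seed + 1))
}
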