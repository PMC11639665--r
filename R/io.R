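# Reading and writing the on-disk formats: FASTA, Vienna three-line records,
# and the tabular dataset manifest that is the package's canonical interchange
# format. All readers return a tibble with columns id / sequence / structure /
# family / split so results chain directly into the rest of the pipeline.

MANIFEST_COLS <- c("id", "sequence", "structure", "family", "split")
SPLIT_LEVELS <- c("train", "val", "test")

#' Normalize an RNA sequence string
#'
#' Uppercases, maps T to U (DNA-alphabet exports are common), and maps any
#' remaining non-ACGU character to the sentinel `N`. Idempotent.
#'
#' @param x Character vector of sequences.
#' @return Character vector of normalized sequences over `{A,C,G,U,N}`.
#' @export
#' @examples
#' normalize_rna("acgt")  # "ACGU"
normalize_rna <- function(x) {
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  gsub("[^ACGU]", "N", x)
}

new_manifest <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("ncrna_manifest", class(df))
  df
}

validate_records <- function(df, where = "input") {
  bad_len <- !is.na(df$structure) & nchar(df$structure) != nchar(df$sequence)
  if (any(bad_len)) {
    abort(sprintf(
      "structure/sequence length mismatch in %s for record(s): %s",
      where, paste(df$id[bad_len], collapse = ", ")))
  }
  invisible(df)
}

#' Read a FASTA file of RNA sequences
#'
#' Sequences are normalized (`T` mapped to `U`, uppercase); structure and
#' family are absent in FASTA so those columns are `NA`.
#'
#' @param path Path to a FASTA file.
#' @param max_frac_unknown Maximum tolerated fraction of characters outside
#'   `{A,C,G,U,N,T}` per record before the record is rejected.
#' @return A manifest tibble (`id`, `sequence`, `structure`, `family`,
#'   `split`), one row per FASTA record.
#' @export
read_fasta <- function(path, max_frac_unknown = 0.1) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  if (!any(startsWith(raw, ">"))) {
    abort(sprintf("no FASTA headers found in %s", path))
  }
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- unname(as.character(seqs))
  frac_bad <- vapply(chars, function(s) {
    n <- nchar(s)
    if (n == 0) return(0)
    ok <- nchar(gsub("[^ACGUNTacgunt]", "", s))
    (n - ok) / n
  }, numeric(1), USE.NAMES = FALSE)
  if (any(frac_bad > max_frac_unknown)) {
    abort(sprintf(
      "record(s) with >%d%% non-ACGUNT characters: %s",
      round(100 * max_frac_unknown),
      paste(ids[frac_bad > max_frac_unknown], collapse = ", ")))
  }
  n_t <- sum(vapply(chars, function(s) nchar(gsub("[^Tt]", "", s)),
                    numeric(1), USE.NAMES = FALSE))
  if (n_t > 0) {
    rlang::inform(sprintf("read_fasta: mapped %d T characters to U", n_t),
                  class = "rnafuse_t_to_u")
  }
  new_manifest(tibble::tibble(
    id = ids,
    sequence = normalize_rna(chars),
    structure = NA_character_,
    family = NA_character_,
    split = NA_character_))
}

#' Read Vienna-style three-line dot-bracket records
#'
#' Each record is a `>` header line, a sequence line and a structure line in
#' dot-bracket notation. Structures are validated for length and balanced
#' brackets (via [parse_dot_bracket()]).
#'
#' @param path Path to a Vienna file.
#' @return A manifest tibble with the `structure` column filled.
#' @export
read_vienna <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("empty Vienna file: %s", path))
  if (length(lines) %% 3 != 0 || !all(startsWith(lines[seq(1, length(lines), by = 3)], ">"))) {
    abort("malformed Vienna file: expected repeating >header / sequence / structure blocks")
  }
  idx <- seq(1, length(lines), by = 3)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[idx]))
  seqs <- normalize_rna(lines[idx + 1])
  structs <- trimws(lines[idx + 2])
  df <- tibble::tibble(id = ids, sequence = seqs, structure = structs,
                       family = NA_character_, split = NA_character_)
  validate_records(df, where = path)
  for (i in seq_len(nrow(df))) parse_dot_bracket(df$structure[i])
  new_manifest(df)
}

#' Read a dataset manifest (TSV or CSV)
#'
#' The manifest is the package's canonical interchange format: columns
#' `id`, `sequence`, `structure`, `family`, `split`. `structure` cells may be
#' empty. Family labels must come from [ncrna_families]; split tags from
#' `train`/`val`/`test`.
#'
#' @param path Path to the manifest file.
#' @param fmt `"tsv"` (default) or `"csv"`.
#' @return A validated manifest tibble in file order.
#' @export
read_manifest <- function(path, fmt = c("tsv", "csv")) {
  fmt <- rlang::arg_match(fmt)
  reader <- if (fmt == "tsv") readr::read_tsv else readr::read_csv
  df <- reader(path, col_types = readr::cols(.default = readr::col_character()),
               progress = FALSE)
  missing_cols <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("manifest is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df <- df[MANIFEST_COLS]
  df$sequence <- normalize_rna(df$sequence)
  df$structure[!is.na(df$structure) & df$structure == ""] <- NA_character_
  df$family[!is.na(df$family) & df$family == ""] <- NA_character_
  df$split[!is.na(df$split) & df$split == ""] <- NA_character_
  as_ncrna_manifest(df)
}

#' Coerce and validate a data frame as an ncRNA manifest
#'
#' @param df Data frame with columns `id`, `sequence`, `structure`, `family`,
#'   `split`.
#' @return A validated manifest tibble.
#' @export
as_ncrna_manifest <- function(df) {
  df <- tibble::as_tibble(df)[MANIFEST_COLS]
  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate record id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  bad_fam <- setdiff(stats::na.omit(unique(df$family)), ncrna_families)
  if (length(bad_fam) > 0) {
    abort(sprintf("unknown family label(s): %s (allowed: %s)",
                  paste(bad_fam, collapse = ", "),
                  paste(ncrna_families, collapse = ", ")))
  }
  bad_split <- setdiff(stats::na.omit(unique(df$split)), SPLIT_LEVELS)
  if (length(bad_split) > 0) {
    abort(sprintf("unknown split tag(s): %s (allowed: %s)",
                  paste(bad_split, collapse = ", "),
                  paste(SPLIT_LEVELS, collapse = ", ")))
  }
  validate_records(df, where = "manifest")
  new_manifest(df)
}

#' Write a dataset manifest
#'
#' Round-trips with [read_manifest()]: `read_manifest(write_manifest(m))`
#' recovers `m` exactly for normalized records.
#'
#' @param manifest Manifest tibble.
#' @param path Output path.
#' @param fmt `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, fmt = c("tsv", "csv")) {
  fmt <- rlang::arg_match(fmt)
  manifest <- as_ncrna_manifest(manifest)
  writer <- if (fmt == "tsv") readr::write_tsv else readr::write_csv
  writer(manifest, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write records as FASTA
#' @param manifest Manifest tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(manifest))) {
    writeLines(c(paste0(">", manifest$id[i]), manifest$sequence[i]), con)
  }
  invisible(path)
}

#' Write records with structures as Vienna three-line blocks
#' @param manifest Manifest tibble; rows without structure are skipped.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(manifest, path) {
  keep <- !is.na(manifest$structure)
  m <- manifest[keep, ]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(c(paste0(">", m$id[i]), m$sequence[i], m$structure[i]), con)
  }
  invisible(path)
}
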