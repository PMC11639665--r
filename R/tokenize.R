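# k-mer tokenization and MLM masking. Sequences are cut into overlapping
# k-mers (stride 1), mapped into a fixed vocabulary of all 4^k k-mers plus
# five specials, wrapped with CLS/SEP, padded to a fixed length, and (for
# pre-training) corrupted with BERT-style 80/10/10 masking.

SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")
MLM_IGNORE <- -1L

#' Cut a sequence into overlapping k-mers
#'
#' @param sequence Normalized RNA string, length at least `k`.
#' @param k k-mer length.
#' @return Character vector of `nchar(sequence) - k + 1` k-mers.
#' @export
kmerize <- function(sequence, k) {
  L <- nchar(sequence)
  if (L < k) abort(sprintf("sequence length %d < k = %d", L, k))
  starts <- seq_len(L - k + 1)
  substring(sequence, starts, starts + k - 1)
}

#' Build the k-mer vocabulary
#'
#' Deterministic ordering: the five specials `[PAD] [UNK] [CLS] [SEP] [MASK]`
#' get ids 0..4, then all `4^k` k-mers in lexicographic order over
#' `A < C < G < U`. Total size `4^k + 5`.
#'
#' @param k k-mer length, between 1 and 8.
#' @return An object of class `rna_vocab`: list with `k`, `tokens`
#'   (id-ordered), `ids` (named integer vector token -> 0-based id), `size`.
#' @export
build_vocab <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > 8 || k != round(k)) {
    abort("k must be an integer in [1, 8]")
  }
  k <- as.integer(k)
  kmers <- do.call(paste0, expand.grid(
    rev(replicate(k, NT_LEVELS, simplify = FALSE)))[, k:1, drop = FALSE])
  kmers <- sort(kmers, method = "radix")
  tokens <- c(SPECIAL_TOKENS, kmers)
  ids <- stats::setNames(seq_along(tokens) - 1L, tokens)
  structure(list(k = k, tokens = tokens, ids = ids,
                 size = length(tokens)), class = "rna_vocab")
}

#' @export
print.rna_vocab <- function(x, ...) {
  cat(sprintf("<rna_vocab: k = %d, size = %d (4^k + 5)>\n", x$k, x$size))
  invisible(x)
}

vocab_special <- function(vocab, tok) unname(vocab$ids[[tok]])

# First content id (all ids >= this are real k-mers).
vocab_content_start <- function(vocab) length(SPECIAL_TOKENS)

#' Encode a sequence into fixed-length token ids
#'
#' Produces `[CLS] kmer... [SEP]` then pads with `[PAD]` to exactly
#' `max_len`. If the sequence yields more than `max_len - 2` k-mers the 5'
#' (leftmost) k-mers are kept and `[SEP]` remains the last real token. Any
#' k-mer containing `N` maps to `[UNK]`.
#'
#' @param sequence Normalized RNA string.
#' @param vocab An `rna_vocab`.
#' @param max_len Total encoded length including specials (at least 3).
#' @return List of class `rna_tokens`: `ids` (0-based integer vector of
#'   length `max_len`) and `attention_mask` (1 on real tokens, 0 on padding).
#' @export
encode_tokens <- function(sequence, vocab, max_len) {
  if (max_len < 3) abort("max_len must be at least 3")
  km <- kmerize(sequence, vocab$k)
  ids <- unname(vocab$ids[km])
  ids[is.na(ids)] <- vocab_special(vocab, "[UNK]")
  if (length(ids) > max_len - 2) ids <- ids[seq_len(max_len - 2)]
  ids <- c(vocab_special(vocab, "[CLS]"), ids, vocab_special(vocab, "[SEP]"))
  mask <- rep(1L, length(ids))
  pad <- max_len - length(ids)
  if (pad > 0) {
    ids <- c(ids, rep(vocab_special(vocab, "[PAD]"), pad))
    mask <- c(mask, rep(0L, pad))
  }
  structure(list(ids = as.integer(ids), attention_mask = mask),
            class = "rna_tokens")
}

#' Reconstruct a sequence from its token ids
#'
#' Inverse of [encode_tokens()] for N-free, untruncated sequences: overlapping
#' k-mers are redundant, so the sequence is the first character of each k-mer
#' plus the tail of the last one.
#'
#' @param tokens An `rna_tokens` object.
#' @param vocab The vocabulary used to encode.
#' @return The decoded sequence string.
#' @export
decode_tokens <- function(tokens, vocab) {
  ids <- tokens$ids[tokens$attention_mask == 1]
  ids <- ids[ids >= vocab_content_start(vocab)]
  km <- vocab$tokens[ids + 1]
  if (length(km) == 0) return("")
  paste0(paste(substr(km, 1, 1), collapse = ""),
         substr(km[length(km)], 2, vocab$k))
}

#' BERT-style MLM corruption of a token sequence
#'
#' Each content token (everything except `[CLS]`, `[SEP]`, `[PAD]`) is
#' selected independently with probability `rate`. Of the selected tokens 80%
#' are replaced with `[MASK]`, 10% with a random k-mer id and 10% kept
#' unchanged. Labels carry the original id at selected positions and the
#' ignore marker (-1) elsewhere. Uses the current RNG state: seed with
#' `set.seed()` for reproducibility.
#'
#' @param tokens An `rna_tokens` object.
#' @param vocab The vocabulary.
#' @param rate Masking rate in (0, 1); the pre-training default is 0.15.
#' @return List with `ids` (corrupted), `labels`, `attention_mask`,
#'   `n_selected`.
#' @export
mask_tokens <- function(tokens, vocab, rate = 0.15) {
  if (!is.numeric(rate) || rate <= 0 || rate >= 1) {
    abort("masking rate must lie strictly between 0 and 1")
  }
  ids <- tokens$ids
  specials <- c(vocab_special(vocab, "[PAD]"), vocab_special(vocab, "[CLS]"),
                vocab_special(vocab, "[SEP]"))
  candidate <- tokens$attention_mask == 1 & !(ids %in% specials)
  labels <- rep(MLM_IGNORE, length(ids))
  sel <- which(candidate & runif(length(ids)) < rate)
  if (length(sel) > 0) {
    labels[sel] <- ids[sel]
    u <- runif(length(sel))
    to_mask <- sel[u < 0.8]
    to_rand <- sel[u >= 0.8 & u < 0.9]
    ids[to_mask] <- vocab_special(vocab, "[MASK]")
    if (length(to_rand) > 0) {
      ids[to_rand] <- sample(seq(vocab_content_start(vocab), vocab$size - 1),
                             length(to_rand), replace = TRUE)
    }
  }
  list(ids = as.integer(ids), labels = as.integer(labels),
       attention_mask = tokens$attention_mask, n_selected = length(sel))
}
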