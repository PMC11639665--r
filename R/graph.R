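# Nucleotide graph construction: one node per nucleotide carrying a 15-dim
# feature vector, backbone edges along the chain and structural edges for
# base pairs (pseudoknots included), with Kipf-style symmetric degree
# normalization (self-loops added) producing the edge weights used by the GCN.

NT_LEVELS <- c("A", "C", "G", "U")
NODE_FEATURE_DIM <- 15L

one_hot_nt <- function(ch) {
  m <- matrix(0, length(ch), 4)
  idx <- match(ch, NT_LEVELS)  # N (or anything else) -> NA -> all-zero row
  ok <- which(!is.na(idx))
  m[cbind(ok, idx[ok])] <- 1
  m
}

#' Per-nucleotide node feature matrix
#'
#' Feature layout per position (15 columns): one-hot of the nucleotide (4),
#' one-hot of the 5' neighbor (4, zeros at the 5' end), one-hot of the 3'
#' neighbor (4, zeros at the 3' end), paired flag (1), pseudoknot-member flag
#' (1), and normalized position `(i-1)/(L-1)` (1; defined as 0 for `L == 1`).
#' `N` nucleotides get an all-zero category block.
#'
#' @param sequence Normalized RNA sequence string.
#' @param pairs Pair tibble from [parse_dot_bracket()].
#' @return An `L x 15` numeric matrix.
#' @export
rna_node_features <- function(sequence, pairs) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(ch)
  if (L == 0) abort("empty sequence")
  if (nrow(pairs) > 0 && (max(pairs$pos3) > L || min(pairs$pos5) < 1)) {
    abort("pair index outside sequence length")
  }
  self <- one_hot_nt(ch)
  left <- rbind(matrix(0, 1, 4), self[-L, , drop = FALSE])
  right <- rbind(self[-1, , drop = FALSE], matrix(0, 1, 4))
  paired <- numeric(L); pk <- numeric(L)
  paired[c(pairs$pos5, pairs$pos3)] <- 1
  pk[c(pairs$pos5[pairs$pseudoknot], pairs$pos3[pairs$pseudoknot])] <- 1
  pos <- if (L == 1) 0 else (seq_len(L) - 1) / (L - 1)
  cbind(self, left, right, paired, pk, pos, deparse.level = 0)
}

#' Build the nucleotide graph for one molecule
#'
#' Nodes are nucleotides; backbone edges connect consecutive positions
#' (`L - 1` of them), structural edges connect each base pair (including
#' pseudoknots). Edges are undirected, stored once with `pos5 < pos3`.
#' [graph_adjacency()] attaches normalized weights.
#'
#' @param sequence Normalized RNA sequence string.
#' @param pairs Pair tibble from [parse_dot_bracket()]; may be empty.
#' @param extra_features Optional `L x p` matrix of extra per-nucleotide
#'   feature columns appended to the standard 15.
#' @return An object of class `ncrna_graph`: list with `node_features`
#'   (`L x d_node`), `edges` (tibble `from`, `to`, `type`, `weight`),
#'   `n_nodes`, and the normalized `adjacency` matrix.
#' @export
build_rna_graph <- function(sequence, pairs = NULL, extra_features = NULL) {
  if (is.null(pairs)) pairs <- parse_dot_bracket(strrep(".", nchar(sequence)))
  L <- nchar(sequence)
  if (L == 0) abort("empty sequence")
  X <- rna_node_features(sequence, pairs)
  if (!is.null(extra_features)) {
    stopifnot(nrow(extra_features) == L)
    X <- cbind(X, extra_features)
  }
  edges <- tibble::tibble(
    from = c(seq_len(max(L - 1, 0)), pairs$pos5),
    to = c(seq_len(max(L - 1, 0)) + 1, pairs$pos3),
    type = c(rep("backbone", max(L - 1, 0)), rep("structural", nrow(pairs))),
    weight = NA_real_)
  g <- structure(
    list(node_features = X, edges = edges, n_nodes = L, adjacency = NULL),
    class = "ncrna_graph")
  graph_adjacency(g)
}

#' Symmetric degree-normalized weighted adjacency
#'
#' Adds a self-loop to every node, then weights edge `(u, v)` as
#' `1 / sqrt(deg(u) * deg(v))` with degrees counting the self-loop and each
#' distinct neighbor once. The result is exactly symmetric with entries in
#' `(0, 1]`.
#'
#' @param graph An `ncrna_graph`.
#' @return The graph with its `adjacency` matrix filled and per-edge weights
#'   written into the `edges` tibble.
#' @export
graph_adjacency <- function(graph) {
  L <- graph$n_nodes
  A <- matrix(0, L, L)
  if (nrow(graph$edges) > 0) {
    A[cbind(graph$edges$from, graph$edges$to)] <- 1
    A[cbind(graph$edges$to, graph$edges$from)] <- 1
  }
  diag(A) <- 1
  deg <- rowSums(A)
  dinv <- 1 / sqrt(deg)
  W <- A * outer(dinv, dinv)
  graph$adjacency <- W
  if (nrow(graph$edges) > 0) {
    graph$edges$weight <- W[cbind(graph$edges$from, graph$edges$to)]
  }
  graph
}

#' @export
print.ncrna_graph <- function(x, ...) {
  cat(sprintf("<ncrna_graph: %d nodes, %d backbone + %d structural edges>\n",
              x$n_nodes, sum(x$edges$type == "backbone"),
              sum(x$edges$type == "structural")))
  invisible(x)
}

#' Export a graph as JSON for inspection
#'
#' Writes `{nodes: [[...feature rows...]], edges: [[from, to, type, weight]]}`.
#'
#' @param graph An `ncrna_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  obj <- list(
    n_nodes = graph$n_nodes,
    nodes = unname(apply(graph$node_features, 1, as.numeric, simplify = FALSE)),
    edges = unname(purrr::pmap(graph$edges, function(from, to, type, weight) {
      list(from, to, type, weight)
    })))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
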