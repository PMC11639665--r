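# Dot-bracket secondary-structure parsing. Matched brackets are base pairs;
# '.' is unpaired. Beyond the primary '(' ')' class, the classes '[]', '{}',
# '<>' and Aa..Zz encode pairs that cross the primary nesting, i.e.
# pseudoknots. Parsing is per-class stack matching; any pair opened by a
# non-'(' class is flagged as a pseudoknot pair (no geometric crossing test).

DB_OPENERS <- c("(", "[", "{", "<", LETTERS)
DB_CLOSERS <- c(")", "]", "}", ">", letters)

#' Parse a dot-bracket string into a base-pair table
#'
#' @param db Dot-bracket string over `.`, `()`, `[]`, `{}`, `<>` and `Aa`-`Zz`
#'   bracket classes; each class must be balanced.
#' @return A tibble with columns `pos5`, `pos3` (1-based pair indices,
#'   `pos5 < pos3`) and `pseudoknot` (`TRUE` if the pair was opened by a
#'   non-`(` bracket class), ordered by `pos5`.
#' @export
#' @examples
#' parse_dot_bracket("((..))")
parse_dot_bracket <- function(db) {
  stopifnot(is.character(db), length(db) == 1)
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  n <- length(ch)
  open_class <- match(ch, DB_OPENERS)
  close_class <- match(ch, DB_CLOSERS)
  illegal <- which(ch != "." & is.na(open_class) & is.na(close_class))
  if (length(illegal) > 0) {
    abort(sprintf("illegal character '%s' at position %d in dot-bracket string",
                  ch[illegal[1]], illegal[1]))
  }
  stacks <- vector("list", length(DB_OPENERS))
  p5 <- integer(0); p3 <- integer(0); cls <- integer(0)
  for (i in seq_len(n)) {
    oc <- open_class[i]
    if (!is.na(oc)) {
      stacks[[oc]] <- c(stacks[[oc]], i)
    } else if (!is.na(close_class[i])) {
      cc <- close_class[i]
      s <- stacks[[cc]]
      if (length(s) == 0) {
        abort(sprintf("unbalanced dot-bracket: '%s' at position %d closes nothing",
                      ch[i], i))
      }
      p5 <- c(p5, s[length(s)]); p3 <- c(p3, i); cls <- c(cls, cc)
      stacks[[cc]] <- s[-length(s)]
    }
  }
  left <- which(lengths(stacks) > 0)
  if (length(left) > 0) {
    pos <- stacks[[left[1]]][1]
    abort(sprintf("unbalanced dot-bracket: '%s' opened at position %d is never closed",
                  DB_OPENERS[left[1]], pos))
  }
  ord <- order(p5)
  tibble::tibble(pos5 = p5[ord], pos3 = p3[ord], pseudoknot = (cls != 1L)[ord])
}

#' Render a base-pair table back to dot-bracket notation
#'
#' The inverse of [parse_dot_bracket()] for structures whose pairs are
#' non-crossing within each flag class: nested pairs are written with `()`,
#' pseudoknot-flagged pairs with `[]`.
#'
#' @param pairs Pair tibble as returned by [parse_dot_bracket()].
#' @param n Sequence length.
#' @return A dot-bracket string of length `n`.
#' @export
render_dot_bracket <- function(pairs, n) {
  out <- rep(".", n)
  if (nrow(pairs) > 0) {
    if (any(pairs$pos5 >= pairs$pos3) || any(pairs$pos3 > n) || any(pairs$pos5 < 1)) {
      abort("invalid pair indices for render_dot_bracket")
    }
    nest <- !pairs$pseudoknot
    out[pairs$pos5[nest]] <- "("; out[pairs$pos3[nest]] <- ")"
    out[pairs$pos5[!nest]] <- "["; out[pairs$pos3[!nest]] <- "]"
  }
  paste(out, collapse = "")
}
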