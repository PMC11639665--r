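# Evaluation: confusion matrix, accuracy, macro-averaged precision / recall /
# F1, and the multiclass Matthews correlation coefficient (Gorodkin's R_K
# statistic computed from the confusion matrix). Macro averaging treats every
# family equally regardless of its size; per-class 0/0 ratios are defined as
# 0 (the harsher convention), as is a degenerate MCC denominator.

#' Evaluate predictions against truth
#'
#' @param truth Character vector (or factor) of true family labels.
#' @param estimate Character vector of predicted labels, aligned with
#'   `truth`.
#' @param levels Label vocabulary fixing the confusion-matrix order; defaults
#'   to [ncrna_families].
#' @return An object of class `rnafuse_eval`: `confusion` (rows = truth,
#'   cols = predicted), `overall` (one-row tibble with `acc`, `precision`,
#'   `recall`, `f1`, `mcc`, `n`), and `per_class`.
#' @export
rna_evaluate <- function(truth, estimate, levels = ncrna_families) {
  if (length(truth) != length(estimate)) {
    abort("truth and estimate differ in length")
  }
  truth <- factor(as.character(truth), levels = levels)
  estimate <- factor(as.character(estimate), levels = levels)
  if (anyNA(truth) || anyNA(estimate)) {
    abort("labels outside the supplied level vocabulary")
  }
  conf <- table(truth = truth, predicted = estimate)
  conf <- matrix(as.integer(conf), nrow(conf), ncol(conf),
                 dimnames = dimnames(conf))
  metrics_from_confusion(conf)
}

# All metrics from a (truth x predicted) confusion matrix.
metrics_from_confusion <- function(conf) {
  s <- sum(conf)
  tp <- diag(conf)
  t_k <- rowSums(conf)   # true counts per class
  p_k <- colSums(conf)   # predicted counts per class
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  prec <- safe_div(tp, p_k)
  rec <- safe_div(tp, t_k)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  # Gorodkin's multiclass MCC
  num <- s * sum(tp) - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  mcc <- if (den == 0) 0 else num / den
  per_class <- tibble::tibble(
    class = rownames(conf) %||% as.character(seq_len(nrow(conf))),
    n = as.integer(t_k), tp = as.integer(tp),
    precision = prec, recall = rec, f1 = f1)
  overall <- tibble::tibble(
    acc = sum(tp) / s, precision = mean(prec), recall = mean(rec),
    f1 = mean(f1), mcc = mcc, n = as.integer(s))
  structure(list(confusion = conf, overall = overall, per_class = per_class),
            class = "rnafuse_eval")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rnafuse_eval <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "<rnafuse_eval: n=%d  ACC=%.4f  precision=%.4f  recall=%.4f  F1=%.4f  MCC=%.4f>\n",
    o$n, o$acc, o$precision, o$recall, o$f1, o$mcc))
  invisible(x)
}

#' Tidy per-class metrics
#' @param x An `rnafuse_eval`.
#' @param ... Unused.
#' @return Tibble with one row per class: `class`, `n`, `tp`, `precision`,
#'   `recall`, `f1`.
#' @export
tidy.rnafuse_eval <- function(x, ...) x$per_class

#' One-row summary of an evaluation
#' @param x An `rnafuse_eval`.
#' @param ... Unused.
#' @return One-row tibble: `acc`, `precision`, `recall`, `f1`, `mcc`, `n`.
#' @export
glance.rnafuse_eval <- function(x, ...) x$overall

#' Fine-tuning history of a model, tidied
#' @param x A fine-tuned `rnafuse_model`.
#' @param ... Unused.
#' @return Long tibble of per-epoch losses and validation accuracy.
#' @export
tidy.rnafuse_model <- function(x, ...) {
  if (is.null(x$history)) abort("model has no fine-tuning history")
  tidyr::pivot_longer(x$history, -"epoch",
                      names_to = "metric", values_to = "value")
}

#' One-row model summary
#' @param x A fine-tuned `rnafuse_model`.
#' @param ... Unused.
#' @return One-row tibble: preset, dims, epochs trained, best validation
#'   accuracy.
#' @export
glance.rnafuse_model <- function(x, ...) {
  tibble::tibble(
    preset = x$config$preset, dim = x$config$dim,
    layers = x$config$layers, alpha = x$config$alpha,
    epochs = if (is.null(x$history)) 0L else max(x$history$epoch),
    best_val_acc = if (is.null(x$history)) NA_real_ else max(x$history$val_acc))
}

#' Confusion-matrix heatmap
#' @param object An `rnafuse_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rnafuse_eval <- function(object, ...) {
  df <- tibble::as_tibble(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted family", y = "true family", fill = "count") +
    ggplot2::theme_minimal()
}

#' Training-curve plot for a model
#' @param object A `rnafuse_model` with pre-training and/or fine-tuning
#'   history.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rnafuse_model <- function(object, ...) {
  if (!is.null(object$history)) {
    df <- tidy.rnafuse_model(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     color = .data$metric)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "epoch", y = NULL, color = NULL) +
      ggplot2::theme_minimal()
  } else if (!is.null(object$pretrain_history)) {
    ggplot2::ggplot(object$pretrain_history,
                    ggplot2::aes(x = .data$step, y = .data$mlm_loss)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "pre-training step", y = "MLM loss") +
      ggplot2::theme_minimal()
  } else {
    abort("model has no training history to plot")
  }
}
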