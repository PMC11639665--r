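# Independent oracles used to check the package implementations. These are
# deliberately written as different algorithms from the ones in R/: the
# dot-bracket oracle repeatedly collapses innermost pairs instead of running
# one stack pass, and the metrics oracle works from label vectors with naive
# per-class loops.

ORACLE_OPENERS <- c("(", "[", "{", "<", LETTERS)
ORACLE_CLOSERS <- c(")", "]", "}", ">", letters)

# Brute-force per-class matcher: for each bracket class, repeatedly find an
# opener whose next same-class bracket is a closer and pair them off.
oracle_parse_db <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  out <- NULL
  for (cl in seq_along(ORACLE_OPENERS)) {
    idx <- which(ch == ORACLE_OPENERS[cl] | ch == ORACLE_CLOSERS[cl])
    sym <- ch[idx]
    repeat {
      hit <- NULL
      for (j in seq_along(sym)) {
        if (j < length(sym) && sym[j] == ORACLE_OPENERS[cl] &&
            sym[j + 1] == ORACLE_CLOSERS[cl]) { hit <- j; break }
      }
      if (is.null(hit)) break
      out <- rbind(out, c(idx[hit], idx[hit + 1], cl != 1))
      keep <- setdiff(seq_along(sym), c(hit, hit + 1))
      idx <- idx[keep]; sym <- sym[keep]
    }
    if (length(sym) > 0) stop("oracle: unbalanced class ", cl)
  }
  if (is.null(out)) {
    return(data.frame(pos5 = integer(0), pos3 = integer(0),
                      pseudoknot = logical(0)))
  }
  out <- out[order(out[, 1]), , drop = FALSE]
  data.frame(pos5 = as.integer(out[, 1]), pos3 = as.integer(out[, 2]),
             pseudoknot = as.logical(out[, 3]))
}

# Random balanced multi-class dot-bracket string: place random pairs (opener
# always before closer), which is balanced per class by construction.
random_balanced_db <- function(len, n_classes = 3, pair_frac = 0.3) {
  ch <- rep(".", len)
  free <- seq_len(len)
  n_pairs <- floor(len * pair_frac / 2)
  for (i in seq_len(n_pairs)) {
    if (length(free) < 2) break
    pos <- sort(sample(free, 2))
    cl <- sample.int(n_classes, 1)
    ch[pos[1]] <- ORACLE_OPENERS[cl]
    ch[pos[2]] <- ORACLE_CLOSERS[cl]
    free <- setdiff(free, pos)
  }
  paste(ch, collapse = "")
}

# Naive metrics from label vectors (independent of metrics_from_confusion).
oracle_metrics <- function(truth, pred, levels) {
  n <- length(truth)
  acc <- mean(truth == pred)
  prec <- rec <- f1 <- numeric(length(levels))
  for (i in seq_along(levels)) {
    cl <- levels[i]
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[i] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[i] <- if (prec[i] + rec[i] == 0) 0 else 2 * prec[i] * rec[i] / (prec[i] + rec[i])
  }
  # MCC via the covariance form over indicator matrices
  X <- outer(truth, levels, "==") * 1
  Y <- outer(pred, levels, "==") * 1
  cov_xy <- sum(diag(crossprod(Y, X))) / n - sum(colMeans(Y) * colMeans(X))
  cov_xx <- sum(diag(crossprod(X, X))) / n - sum(colMeans(X)^2)
  cov_yy <- sum(diag(crossprod(Y, Y))) / n - sum(colMeans(Y)^2)
  mcc <- if (cov_xx == 0 || cov_yy == 0) 0 else cov_xy / sqrt(cov_xx * cov_yy)
  list(acc = acc, precision = mean(prec), recall = mean(rec),
       f1 = mean(f1), mcc = mcc)
}

# Draw a random confusion matrix and expand it to label vectors.
random_confusion_labels <- function(C = 4, max_count = 8) {
  conf <- matrix(rpois(C * C, 2), C, C)
  if (sum(conf) == 0) conf[1, 1] <- 1
  levels <- paste0("c", seq_len(C))
  truth <- rep(rep(levels, each = C), times = as.vector(t(conf)))
  pred <- rep(rep(levels, times = C), times = as.vector(t(conf)))
  list(conf = conf, truth = truth, pred = pred, levels = levels)
}

# Finite-difference gradient check helper: returns the max relative error
# over sampled coordinates, skipping coordinates near a ReLU kink where the
# two-sided difference is invalid.
max_grad_err <- function(par, grads, loss_fn, n_coord = 3, eps = 1e-6) {
  worst <- 0
  for (nm in names(grads)) {
    p <- par[[nm]]
    for (i in sample(length(p), min(n_coord, length(p)))) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      err <- abs(num - grads[[nm]][i]) / max(1, abs(num))
      worst <- max(worst, err)
    }
  }
  worst
}

desk_tiny <- function(...) {
  rna_config("desk", dim = 8L, heads = 2L, layers = 2L, ffn = 12L,
             max_len = 24L, k = 1L, gcn_layers = 2L, gcn_hidden = 6L,
             dz = 5L, ...)
}
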