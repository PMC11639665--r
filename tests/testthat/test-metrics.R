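test_that("perfect predictions score 1 on every metric", {
  y <- rep(ncrna_families, times = 3)
  ev <- rna_evaluate(y, y)
  o <- glance(ev)
  expect_equal(o$acc, 1); expect_equal(o$precision, 1)
  expect_equal(o$recall, 1); expect_equal(o$f1, 1); expect_equal(o$mcc, 1)
  expect_equal(sum(ev$confusion), length(y))
  expect_equal(sum(diag(ev$confusion)), length(y))
})

test_that("degenerate all-one-class predictions give MCC 0", {
  truth <- rep(c("tRNA", "rRNA"), each = 5)
  pred <- rep("tRNA", 10)
  ev <- rna_evaluate(truth, pred, levels = c("rRNA", "tRNA"))
  expect_equal(glance(ev)$mcc, 0)
  expect_equal(glance(ev)$acc, 0.5)
})

test_that("hand-worked confusion matrix [[2,1],[0,3]] scores correctly", {
  truth <- c(rep("rRNA", 3), rep("tRNA", 3))
  pred <- c("rRNA", "rRNA", "tRNA", "tRNA", "tRNA", "tRNA")
  ev <- rna_evaluate(truth, pred, levels = c("rRNA", "tRNA"))
  expect_equal(unname(ev$confusion), rbind(c(2, 1), c(0, 3)))
  o <- glance(ev)
  expect_equal(o$acc, 5 / 6)
  # per class: precision (2/2, 3/4), recall (2/3, 3/3)
  expect_equal(o$precision, mean(c(1, 3 / 4)))
  expect_equal(o$recall, mean(c(2 / 3, 1)))
  f1 <- c(2 * 1 * (2 / 3) / (1 + 2 / 3), 2 * (3 / 4) * 1 / (3 / 4 + 1))
  expect_equal(o$f1, mean(f1))
  # Gorodkin by hand: s=6, c=5, p=(2,4), t=(3,3)
  expect_equal(o$mcc, (6 * 5 - (2 * 3 + 4 * 3)) /
                 sqrt((36 - (4 + 16)) * (36 - (9 + 9))))
})

test_that("metrics agree with an independent oracle on 200 random matrices", {
  set.seed(2024)
  for (i in 1:200) {
    rc <- random_confusion_labels(C = sample(2:7, 1))
    ev <- rna_evaluate(rc$truth, rc$pred, levels = rc$levels)
    o <- glance(ev)
    want <- oracle_metrics(rc$truth, rc$pred, rc$levels)
    expect_equal(o$acc, want$acc, tolerance = 1e-9)
    expect_equal(o$precision, want$precision, tolerance = 1e-9)
    expect_equal(o$recall, want$recall, tolerance = 1e-9)
    expect_equal(o$f1, want$f1, tolerance = 1e-9)
    expect_equal(o$mcc, want$mcc, tolerance = 1e-9)
  }
})

test_that("metrics agree with scikit-learn on random label sets", {
  set.seed(55)
  rc <- random_confusion_labels(C = 5)
  ev <- glance(rna_evaluate(rc$truth, rc$pred, levels = rc$levels))
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(list(truth = rc$truth, pred = rc$pred), tf)
  py <- paste(
    "import json,sys",
    "from sklearn.metrics import accuracy_score,precision_score,recall_score,f1_score,matthews_corrcoef",
    sprintf("d=json.load(open('%s'))", tf),
    "t,p=d['truth'],d['pred']",
    "print(json.dumps({'acc':accuracy_score(t,p),",
    " 'precision':precision_score(t,p,average='macro',zero_division=0),",
    " 'recall':recall_score(t,p,average='macro',zero_division=0),",
    " 'f1':f1_score(t,p,average='macro',zero_division=0),",
    " 'mcc':matthews_corrcoef(t,p)}))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  sk <- jsonlite::fromJSON(out[length(out)])
  expect_equal(ev$acc, sk$acc, tolerance = 1e-9)
  expect_equal(ev$precision, sk$precision, tolerance = 1e-9)
  expect_equal(ev$recall, sk$recall, tolerance = 1e-9)
  expect_equal(ev$f1, sk$f1, tolerance = 1e-9)
  expect_equal(ev$mcc, sk$mcc, tolerance = 1e-9)
})

test_that("accuracy is monotone under correcting a wrong prediction", {
  set.seed(9)
  truth <- sample(ncrna_families, 40, replace = TRUE)
  pred <- sample(ncrna_families, 40, replace = TRUE)
  wrong <- which(pred != truth)
  for (i in head(wrong, 5)) {
    before <- glance(rna_evaluate(truth, pred))$acc
    fixed <- pred; fixed[i] <- truth[i]
    after <- glance(rna_evaluate(truth, fixed))$acc
    expect_gt(after, before)
  }
  expect_error(rna_evaluate(truth, pred[-1]), "length")
})

test_that("tidy and glance return well-formed tibbles", {
  truth <- rep(ncrna_families, times = 2)
  set.seed(10)
  pred <- sample(truth)
  ev <- rna_evaluate(truth, pred)
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$class, ncrna_families)
  expect_named(glance(ev), c("acc", "precision", "recall", "f1", "mcc", "n"))
  expect_s3_class(autoplot(ev), "ggplot")
})
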