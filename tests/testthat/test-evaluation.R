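# Confusion matrices and classification reports

test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2,
                                   dimnames = dimnames(cm)),
               ignore_attr = TRUE)
  # perfect predictions give a diagonal of the supports
  truth <- rep(0:2, times = c(5, 3, 2))
  cm2 <- confusion_matrix(truth, truth, 3)
  expect_equal(diag(unclass(cm2)), c(5L, 3L, 2L), ignore_attr = TRUE)
  expect_equal(sum(cm2) - sum(diag(unclass(cm2))), 0)
  # empty input -> zero matrix
  expect_equal(sum(confusion_matrix(integer(0), integer(0), 3)), 0)
  expect_error(confusion_matrix(c(0, 3), c(0, 1), 3),
               class = "lbpfuse_invalid_input")
  expect_error(confusion_matrix(0, c(0, 1), 2), class = "lbpfuse_invalid_input")
})

test_that("reports agree with an independent reference implementation", {
  skip_if_not_installed("caret")
  set.seed(41)
  for (i in 1:5) {
    k <- sample(3:6, 1)
    n <- 200
    truth <- sample(0:(k - 1), n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, truth, sample(0:(k - 1), n, replace = TRUE))
    rep_ <- classification_report(confusion_matrix(truth, pred, k))
    ref <- caret::confusionMatrix(factor(pred, levels = 0:(k - 1)),
                                  factor(truth, levels = 0:(k - 1)))
    by_class <- ref$byClass
    if (is.null(dim(by_class))) by_class <- t(by_class)
    expect_equal(rep_$per_class$recall,
                 unname(ifelse(is.na(by_class[, "Sensitivity"]), 0,
                               by_class[, "Sensitivity"])), tolerance = 1e-9)
    expect_equal(rep_$per_class$precision,
                 unname(ifelse(is.na(by_class[, "Pos Pred Value"]), 0,
                               by_class[, "Pos Pred Value"])), tolerance = 1e-9)
    expect_equal(rep_$accuracy, unname(ref$overall["Accuracy"]),
                 tolerance = 1e-9)
  }
})

test_that("support-weighted recall equals accuracy exactly", {
  set.seed(42)
  truth <- sample(0:4, 300, replace = TRUE)
  pred <- sample(0:4, 300, replace = TRUE)
  rep_ <- classification_report(confusion_matrix(truth, pred, 5))
  expect_equal(rep_$weighted[["recall"]], rep_$accuracy, tolerance = 1e-12)
})

test_that("permuting classes permutes the report", {
  set.seed(43)
  truth <- sample(0:3, 120, replace = TRUE)
  pred <- sample(0:3, 120, replace = TRUE)
  cm <- confusion_matrix(truth, pred, 4)
  perm <- c(3, 1, 4, 2)
  cmp <- unclass(cm)[perm, perm]
  rep1 <- classification_report(cm)
  rep2 <- classification_report(cmp)
  expect_equal(rep2$per_class$recall, rep1$per_class$recall[perm])
  expect_equal(rep2$per_class$f1, rep1$per_class$f1[perm])
  expect_equal(rep2$macro, rep1$macro)
  expect_equal(rep2$accuracy, rep1$accuracy)
})

test_that("zero denominators yield zero metrics by convention", {
  cm <- matrix(c(3L, 2L, 0L, 0L), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  rep_ <- classification_report(cm)
  expect_equal(rep_$per_class$precision[2], 0)       # empty predicted column
  expect_equal(rep_$per_class$recall[2], 0)
  expect_equal(rep_$per_class$f1[2], 0)
  expect_error(classification_report(matrix(0L, 3, 3)),
               class = "lbpfuse_empty_evaluation")
})

test_that("rendering writes a full-precision report that round-trips", {
  set.seed(44)
  truth <- sample(0:4, 150, replace = TRUE)
  pred <- ifelse(runif(150) < 0.7, truth, sample(0:4, 150, replace = TRUE))
  cm <- confusion_matrix(truth, pred, 5, paste0("k", 1:5))
  rep_ <- classification_report(cm)
  out <- file.path(tempdir(), "render-test")
  files <- render_report(rep_, cm, out)
  expect_true(all(file.exists(file.path(out, c("report.csv", "report.json",
                                               "confusion.png", "metrics.png")))))
  expect_true(all(file.size(file.path(out, c("confusion.png", "metrics.png"))) > 0))
  csv <- read.csv(file.path(out, "report.csv"))
  expect_equal(nrow(csv), 5 + 3)                     # class rows + aggregates
  expect_equal(csv$recall[1:5], rep_$per_class$recall, tolerance = 1e-9)
  expect_equal(csv$f1[8], rep_$accuracy, tolerance = 1e-9)
  expect_error(render_report(rep_, cm, "/dev/null/nope"),
               class = "lbpfuse_io_error")
})

test_that("rendered tables round half-up to two decimals", {
  expect_equal(round_half_up(0.975, 2), 0.98)
  expect_equal(round_half_up(32 / 33, 2), 0.97)
  tab <- lbpfuse:::.report_table(
    classification_report(confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)), 2)
  expect_equal(tab$recall[1], 0.5)
})
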