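# Confusion matrix and the five evaluation indexes.

test_that("confusion matrix counts match hand tallies and conventions", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"),
                         classes = c("A", "B"))
  counts <- unclass(cm)
  attr(counts, "classes") <- NULL
  expect_equal(counts, matrix(c(1L, 0L, 1L, 1L), 2,
                              dimnames = list(real = c("A", "B"),
                                              predicted = c("A", "B"))))
  perfect <- confusion_matrix(rep(c("A", "B"), c(3, 2)),
                              rep(c("A", "B"), c(3, 2)),
                              classes = c("A", "B"))
  expect_equal(diag(unclass(perfect)), c(A = 3L, B = 2L))
  expect_equal(sum(unclass(perfect)) - sum(diag(unclass(perfect))), 0L)
  expect_error(confusion_matrix("A", "C", classes = c("A", "B")),
               "unknown label: C")
  expect_error(confusion_matrix(c("A", "A"), "A", classes = "A"),
               "equal length")
})

test_that("the re-entered reference confusion table totals 2347", {
  cm <- reference_confusion()
  expect_equal(sum(cm), 2347)
  expect_equal(unname(rowSums(unclass(cm))),
               c(369, 100, 960, 66, 422, 371, 59))
})

test_that("the AT row of the reference table reproduces its published metrics", {
  m <- class_metrics(reference_confusion(), "AT")
  expect_equal(m$tp, 100); expect_equal(m$fp, 1); expect_equal(m$fn, 0)
  expect_equal(percent1(m$ppr), 99.0)
  expect_equal(percent1(m$sen), 100.0)
  # Spe = 2246/2247 = 99.96% -> 100.0 at one decimal
  expect_equal(m$tn, 2246)
  expect_equal(percent1(m$spe), 100.0)
  expect_equal(percent1(m$f1), 99.5)
})

test_that("micro accuracy is the trace over the grand total", {
  expect_equal(micro_accuracy(reference_confusion()), 2305 / 2347)
  d <- as_confusion_matrix(diag(c(5L, 3L)), c("x", "y"))
  expect_equal(micro_accuracy(d), 1)
  expect_equal(micro_accuracy(as_confusion_matrix(matrix(1L, 2, 2),
                                                  c("x", "y"))), 0.5)
  expect_error(micro_accuracy(as_confusion_matrix(matrix(0L, 2, 2),
                                                  c("x", "y"))), "empty")
})

test_that("macro averaging matches the published specificity average", {
  spe_printed <- c(99.3, 100.0, 99.5, 99.9, 99.6, 99.7, 99.9)
  expect_equal(macro_average(spe_printed), 99.7)
  expect_equal(macro_average(c(0.9, 1.0) * 100), 95)
  cm <- reference_confusion()
  per <- lapply(attr(cm, "classes"), function(cl) class_metrics(cm, cl))
  avg <- macro_average(per)
  expect_equal(unname(avg["sen"]),
               mean(vapply(per, function(m) m$sen, numeric(1))))
})

test_that("degenerate and undefined metrics are flagged, never imputed", {
  one <- as_confusion_matrix(matrix(7L, 1, 1), "N")
  m <- class_metrics(one, "N")
  expect_equal(m$sen, 1); expect_equal(m$ppr, 1); expect_equal(m$acc, 1)
  expect_true(is.na(m$spe))  # no negatives exist
  avg <- macro_average(list(m))
  expect_true(is.na(avg["spe"]))
  expect_false(is.na(avg["sen"]))
})

test_that("support-weighted sensitivity equals micro accuracy on random matrices", {
  set.seed(31)
  for (k in 1:25) {
    K <- sample(2:6, 1)
    m <- matrix(rpois(K * K, 4), K)
    diag(m) <- diag(m) + rpois(K, 20) + 1  # ensure non-empty rows
    cm <- as_confusion_matrix(m, LETTERS[1:K])
    sen <- vapply(LETTERS[1:K], function(cl) class_metrics(cm, cl)$sen,
                  numeric(1))
    support <- rowSums(m)
    expect_equal(sum(sen * support) / sum(support), micro_accuracy(cm),
                 tolerance = 1e-12)
    # TP+FP is the column total and TP+FN the row total for every class
    for (i in seq_len(K)) {
      cmx <- class_metrics(cm, LETTERS[i])
      expect_equal(cmx$tp + cmx$fp, sum(m[, i]))
      expect_equal(cmx$tp + cmx$fn, sum(m[i, ]))
      expect_equal(cmx$tp + cmx$fp + cmx$fn + cmx$tn, sum(m))
      if (!is.na(cmx$f1)) {
        expect_gte(cmx$f1, min(cmx$ppr, cmx$sen) - 1e-12)
        expect_lte(cmx$f1, max(cmx$ppr, cmx$sen) + 1e-12)
      }
    }
  }
})

test_that("metrics agree whether computed from labels or from the matrix", {
  set.seed(33)
  classes <- c("AF", "N", "PVC")
  y_true <- sample(classes, 200, replace = TRUE)
  y_pred <- ifelse(runif(200) < 0.8, y_true, sample(classes, 200, TRUE))
  cm <- confusion_matrix(y_true, y_pred, classes)
  for (cl in classes) {
    m <- class_metrics(cm, cl)
    expect_equal(m$tp, sum(y_true == cl & y_pred == cl))
    expect_equal(m$sen, sum(y_true == cl & y_pred == cl) / sum(y_true == cl))
  }
  expect_equal(micro_accuracy(cm), mean(y_true == y_pred))
})

test_that("reports round-trip through CSV and print the published AT row", {
  rep <- evaluation_report(reference_confusion())
  expect_equal(nrow(rep$metrics), 8)  # 7 classes + average
  at <- rep$metrics[rep$metrics$class == "AT", ]
  expect_equal(unlist(at[c("ppr", "sen", "spe", "f1")], use.names = FALSE),
               c(99.0, 100.0, 100.0, 99.5))
  expect_equal(rep$metrics$spe[rep$metrics$class == "Average"], 99.7)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  back <- read_confusion_csv(file.path(dir, "confusion.csv"))
  expect_equal(unclass(back), unclass(rep$cm))
  out <- capture.output(print(rep))
  expect_true(any(grepl("98.2% \\(2305/2347\\)", out)))
})

test_that("percentage rounding is half away from zero", {
  expect_equal(round_half_away(99.95, 1), 100.0)
  expect_equal(round_half_away(97.45, 1), 97.5)
  expect_equal(round_half_away(-0.05, 1), -0.1)
  expect_equal(percent1(2305 / 2347), 98.2)
})
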