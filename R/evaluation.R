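# Confusion matrix and the five per-class evaluation indexes: precision
# (Ppr), sensitivity (Sen), specificity (Spe), F1, and accuracy (Acc).
# Rows are the real category, columns the predicted category.

#' Confusion matrix of true vs predicted labels
#'
#' `counts[i, j]` is the number of samples whose real category is
#' `classes[i]` and predicted category is `classes[j]`.
#'
#' @param y_true,y_pred equal-length label vectors, subsets of `classes`.
#' @param classes ordered class labels.
#' @return Object of class `confusion_matrix` (an integer matrix with the
#'   class list attached).
#' @export
confusion_matrix <- function(y_true, y_pred, classes = arrhythmia_classes()) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  unk <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(unk)) stop("unknown label: ", unk[1])
  m <- table(factor(y_true, levels = classes),
             factor(y_pred, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(real = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix"), classes = classes)
}

#' Construct a confusion matrix from pre-tabulated counts
#'
#' For re-entering a printed confusion table (rows = real, columns =
#' predicted).
#'
#' @param counts square matrix of non-negative counts.
#' @param classes class labels in row/column order.
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts, classes = rownames(counts)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (is.null(classes)) classes <- as.character(seq_len(nrow(counts)))
  m <- matrix(as.integer(counts), nrow(counts),
              dimnames = list(real = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix"), classes = classes)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = real, columns = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class counts and the five evaluation indexes
#'
#' For one class: `TP` its diagonal entry, `FP` the rest of its column,
#' `FN` the rest of its row, `TN` everything else. The indexes are
#' `Ppr = TP/(TP+FP)`, `Sen = TP/(TP+FN)`, `Spe = TN/(TN+FP)`,
#' `F1 = 2*Ppr*Sen/(Ppr+Sen)`, `Acc = (TP+TN)/total`. A zero denominator
#' makes the affected index `NA` (flagged, never silently 0).
#'
#' @param cm a `confusion_matrix`.
#' @param cls class name.
#' @return Object of class `class_metrics`: a list with the four counts and
#'   the five indexes as fractions in `[0, 1]`.
#' @export
class_metrics <- function(cm, cls) {
  classes <- attr(cm, "classes")
  k <- match(cls, classes)
  if (is.na(k)) stop("unknown class: ", cls)
  m <- unclass(cm)
  total <- sum(m)
  tp <- m[k, k]
  fp <- sum(m[, k]) - tp
  fn <- sum(m[k, ]) - tp
  tn <- total - tp - fp - fn
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  ppr <- frac(tp, tp + fp)
  sen <- frac(tp, tp + fn)
  f1 <- if (!is.na(ppr) && !is.na(sen) && ppr + sen > 0) {
    2 * ppr * sen / (ppr + sen)
  } else NA_real_
  structure(list(class = cls, tp = tp, fp = fp, fn = fn, tn = tn,
                 ppr = ppr, sen = sen, spe = frac(tn, tn + fp), f1 = f1,
                 acc = frac(tp + tn, total)),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "undefined", sprintf("%.1f%%", percent1(v)))
  cat(sprintf("%s: TP %d FP %d FN %d TN %d | Ppr %s Sen %s Spe %s F1 %s Acc %s\n",
              x$class, x$tp, x$fp, x$fn, x$tn, fmt(x$ppr), fmt(x$sen),
              fmt(x$spe), fmt(x$f1), fmt(x$acc)))
  invisible(x)
}

#' Micro accuracy (trace over grand total)
#'
#' @param cm a `confusion_matrix`.
#' @return Fraction of samples on the diagonal.
#' @export
micro_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(unclass(cm))) / total
}

#' Unweighted macro average of per-class metrics
#'
#' Arithmetic mean over classes of each index. Accepts either a list of
#' [class_metrics()] objects or a numeric vector/matrix of printed values
#' (e.g. percentage columns of a published table). Any undefined (`NA`)
#' input makes the corresponding average `NA`.
#'
#' @param per_class list of `class_metrics`, or numeric values.
#' @return Named numeric vector of averages (same scale as the input), or a
#'   single number for plain numeric input.
#' @export
macro_average <- function(per_class) {
  if (is.numeric(per_class)) {
    return(round_half_away(mean(per_class), 1))
  }
  stopifnot(length(per_class) >= 1)
  keys <- c("ppr", "sen", "spe", "f1", "acc")
  out <- vapply(keys, function(k) {
    vals <- vapply(per_class, function(m) m[[k]], numeric(1))
    mean(vals)  # NA propagates: undefined inputs flag the average
  }, numeric(1))
  out
}

#' Full evaluation report from a confusion matrix
#'
#' Per-class metric rows plus an unweighted average row and the micro
#' accuracy, percentages at one decimal (half away from zero). Undefined
#' entries print as `undefined`.
#'
#' @param cm a `confusion_matrix`.
#' @return Object of class `evaluation_report` with elements `cm`, `metrics`
#'   (data frame of percentages), `micro_accuracy` (fraction).
#' @export
evaluation_report <- function(cm) {
  classes <- attr(cm, "classes")
  per <- lapply(classes, function(cl) class_metrics(cm, cl))
  metrics <- do.call(rbind, lapply(per, function(m) {
    data.frame(class = m$class,
               ppr = percent1(m$ppr), sen = percent1(m$sen),
               spe = percent1(m$spe), f1 = percent1(m$f1),
               acc = percent1(m$acc), stringsAsFactors = FALSE)
  }))
  avg <- macro_average(per)
  metrics <- rbind(metrics,
                   data.frame(class = "Average",
                              ppr = percent1(avg[["ppr"]]),
                              sen = percent1(avg[["sen"]]),
                              spe = percent1(avg[["spe"]]),
                              f1 = percent1(avg[["f1"]]),
                              acc = percent1(avg[["acc"]]),
                              stringsAsFactors = FALSE))
  structure(list(cm = cm, metrics = metrics,
                 micro_accuracy = micro_accuracy(cm)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$cm)
  cat("\nper-class metrics (%):\n")
  out <- x$metrics
  for (col in c("ppr", "sen", "spe", "f1", "acc")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "undefined",
                         sprintf("%.1f", out[[col]]))
  }
  print(out, row.names = FALSE)
  cat(sprintf("\nmicro accuracy: %.1f%% (%d/%d)\n",
              percent1(x$micro_accuracy), sum(diag(unclass(x$cm))),
              sum(x$cm)))
  invisible(x)
}

#' Write an evaluation report to CSV files
#'
#' `confusion.csv` (counts) and `metrics.csv` (percentages) in `dir`.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(unclass(report$cm)),
            file.path(dir, "confusion.csv"))
  write.csv(report$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read back a confusion matrix written by [write_report()]
#'
#' @param path path to `confusion.csv`.
#' @return A `confusion_matrix`.
#' @export
read_confusion_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as_confusion_matrix(as.matrix(df), classes = rownames(df))
}
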