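#' Oversample the minority class
#'
#' Duplicates minority-class indices (sampled with replacement) until both
#' classes have equal counts; every original index is retained. Applied to
#' training data only, so that positive cases carry sufficient weight without
#' the evaluation set ever being resampled.
#'
#' @param y binary label vector (0/1), both classes present.
#' @param rng_seed seed for the duplicate draw.
#' @return integer index multiset into `y`.
#' @export
oversample <- function(y, rng_seed = 1L) {
  y <- as.numeric(y)
  pos <- which(y == 1); neg <- which(y == 0)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("oversampling requires both classes")
  }
  set.seed(rng_seed)
  if (length(pos) == length(neg)) return(seq_along(y))
  minority <- if (length(pos) < length(neg)) pos else neg
  extra <- abs(length(pos) - length(neg))
  c(seq_along(y), sample(minority, extra, replace = TRUE))
}

#' k-fold cross-validation partition
#'
#' @param n number of notes.
#' @param k number of folds (default 5).
#' @param rng_seed shuffle seed.
#' @return list of `k` lists, each with integer vectors `train` and `test`;
#'   test folds are disjoint, exhaustive and differ in size by at most 1.
#' @export
split_kfold <- function(n, k = 5L, rng_seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("need at least k notes")
  set.seed(rng_seed)
  shuffled <- sample.int(n)
  fold_of <- rep_len(seq_len(k), n)
  lapply(seq_len(k), function(f) {
    test <- sort(shuffled[fold_of == f])
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Date-based train/test split
#'
#' Emulates deployment: train on notes strictly before the cutoff date, test
#' on notes on or after it.
#'
#' @param dates vector of note dates (`Date` or ISO-8601 strings).
#' @param cutoff cutoff date; notes dated on/after it form the test set.
#' @return list with integer vectors `train` and `test`; a warning is issued
#'   if either side is empty.
#' @export
split_temporal <- function(dates, cutoff) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("every note needs a parseable date")
  cutoff <- as.Date(cutoff)
  train <- which(dates < cutoff)
  test <- which(dates >= cutoff)
  if (length(train) == 0L) warning("temporal split: empty training side")
  if (length(test) == 0L) warning("temporal split: empty test side")
  list(train = train, test = test)
}

#' ROC area under the curve
#'
#' Computed in its rank (Mann-Whitney) form: the proportion of
#' positive-negative pairs in which the positive note outscores the negative,
#' with ties counting one half.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision, recall and F-measure at a threshold
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F = 2 * precision * recall / (precision + recall)`. When no note is
#' predicted positive, precision (and hence F) is reported as 0 by
#' convention.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1).
#' @param threshold scores strictly greater than this are predicted positive
#'   (0.5 suits probability outputs; 0 suits SVM decision values).
#' @return named numeric vector `precision`, `recall`, `f`.
#' @export
f_measure <- function(scores, labels, threshold = 0.5) {
  labels <- as.numeric(labels)
  pred <- as.numeric(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f = f)
}

#' Aggregate per-task metrics into an evaluation report
#'
#' Produces the standard report shape: one row per chapter task with training
#' and test AUC and F-measure, plus two aggregates per column — the global
#' mean over tasks and the mean of the 5 lowest values (the worst-task
#' summary).
#'
#' @param rows data.frame with columns `task`, `train_auc`, `test_auc`,
#'   `train_f`, `test_f` (and optionally `model`).
#' @return an `icd_eval` object: list with `rows` and `aggregates` (a
#'   data.frame with `statistic` = `"mean"`/`"lowest5_mean"` per metric
#'   column).
#' @export
summarize_eval <- function(rows) {
  metrics <- intersect(c("train_auc", "test_auc", "train_f", "test_f"),
                       names(rows))
  if (nrow(rows) < 5L) {
    warning("fewer than 5 tasks; lowest-5 mean computed over all tasks")
  }
  agg <- do.call(rbind, lapply(c("mean", "lowest5_mean"), function(s) {
    vals <- vapply(metrics, function(m) {
      v <- rows[[m]]
      if (s == "mean") mean(v) else mean(sort(v)[seq_len(min(5L, length(v)))])
    }, numeric(1))
    cbind(data.frame(statistic = s), as.data.frame(as.list(vals)))
  }))
  structure(list(rows = rows, aggregates = agg), class = "icd_eval")
}

#' @export
print.icd_eval <- function(x, digits = 4, ...) {
  cat("Per-task evaluation (", nrow(x$rows), " task rows)\n", sep = "")
  rows <- x$rows
  num <- vapply(rows, is.numeric, TRUE)
  rows[num] <- lapply(rows[num], round, digits = digits)
  print(rows, row.names = FALSE)
  cat("\nAggregates (global mean and mean of the 5 lowest):\n")
  agg <- x$aggregates
  num <- vapply(agg, is.numeric, TRUE)
  agg[num] <- lapply(agg[num], round, digits = digits)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes the per-task rows as a TSV table and the aggregates as JSON.
#'
#' @param report an `icd_eval` object.
#' @param path_rows TSV output path for the rows.
#' @param path_summary JSON output path for the aggregates (optional).
#' @export
write_eval <- function(report, path_rows, path_summary = NULL) {
  stopifnot(inherits(report, "icd_eval"))
  utils::write.table(report$rows, path_rows, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_summary)) {
    jsonlite::write_json(report$aggregates, path_summary, digits = NA,
                         dataframe = "rows")
  }
  invisible(report)
}
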