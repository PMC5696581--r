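#' Classical bag-of-words baselines
#'
#' Wrappers over the classical classifiers used on the document-term matrix:
#' support vector machines with the four common kernels (`svm_linear`,
#' `svm_poly3` with polynomial degree 3, `svm_rbf`, `svm_sigmoid`), a random
#' forest (`rf`) and a gradient boosting machine (`gbm`, xgboost backend).
#' Backend hyperparameters are left at their defaults; the scores they return
#' are the SVM decision values or the tree-ensemble probabilities, suitable
#' for ROC analysis.
#'
#' @param kind one of `"svm_linear"`, `"svm_poly3"`, `"svm_rbf"`,
#'   `"svm_sigmoid"`, `"rf"`, `"gbm"`.
#' @param x document-term matrix (dense or [Matrix::sparseMatrix]) with
#'   feature column names.
#' @param y binary labels (0/1), both classes present.
#' @param seed RNG seed for the stochastic backends (rf, gbm).
#' @return a `baseline_fit` handle for [score_baseline()].
#' @export
train_baseline <- function(kind, x, y, seed = 1L) {
  kinds <- c("svm_linear", "svm_poly3", "svm_rbf", "svm_sigmoid", "rf", "gbm")
  if (!kind %in% kinds) {
    stop("unknown baseline kind \"", kind, "\"; expected one of: ",
         paste(kinds, collapse = ", "))
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class; cannot fit a classifier")
  }
  xm <- as.matrix(x)
  if (is.null(colnames(xm))) stop("document-term matrix has no column names")
  vocab <- colnames(xm)
  fit <- switch(kind,
    svm_linear = e1071::svm(xm, factor(y, levels = c(0, 1)),
                            kernel = "linear", scale = FALSE),
    svm_poly3 = e1071::svm(xm, factor(y, levels = c(0, 1)),
                           kernel = "polynomial", degree = 3, scale = FALSE),
    svm_rbf = e1071::svm(xm, factor(y, levels = c(0, 1)),
                         kernel = "radial", scale = FALSE),
    svm_sigmoid = e1071::svm(xm, factor(y, levels = c(0, 1)),
                             kernel = "sigmoid", scale = FALSE),
    rf = {
      set.seed(seed)
      randomForest::randomForest(xm, factor(y, levels = c(0, 1)))
    },
    gbm = {
      set.seed(seed)
      xgboost::xgboost(xm, factor(y, levels = c(0, 1)), nrounds = 50,
                       nthreads = 1, verbosity = 0)
    })
  structure(list(kind = kind, fit = fit, vocabulary = vocab),
            class = "baseline_fit")
}

#' @rdname train_baseline
#' @param handle a `baseline_fit` from [train_baseline()].
#' @return `score_baseline` returns a numeric score per note (higher = more
#'   likely positive): SVM decision values oriented toward the positive
#'   class, or ensemble probabilities for rf/gbm.
#' @export
score_baseline <- function(handle, x) {
  stopifnot(inherits(handle, "baseline_fit"))
  xm <- as.matrix(x)
  if (is.null(colnames(xm)) || !identical(colnames(xm), handle$vocabulary)) {
    stop("document-term matrix columns do not match the training vocabulary")
  }
  if (startsWith(handle$kind, "svm")) {
    pr <- stats::predict(handle$fit, xm, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # e1071 orients the decision value toward the first class of the pair
    # named in the column label ("first/second")
    lab <- colnames(dv)[1]
    s <- as.numeric(dv[, 1])
    if (startsWith(lab, "0/")) -s else s
  } else if (handle$kind == "rf") {
    as.numeric(stats::predict(handle$fit, xm, type = "prob")[, "1"])
  } else {
    as.numeric(stats::predict(handle$fit, xm))
  }
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat("Baseline classifier:", x$kind, "|", length(x$vocabulary),
      "features\n")
  invisible(x)
}
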