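#' Shannon entropy of class counts
#'
#' @param counts nonnegative class counts, total > 0.
#' @return entropy in bits: `-sum(p * log2(p))` over nonzero classes.
#' @export
#' @examples
#' entropy_bits(c(5, 5)) # 1 bit
entropy_bits <- function(counts) {
  if (any(counts < 0)) stop("negative class count")
  total <- sum(counts)
  if (total == 0) stop("entropy undefined for all-zero counts")
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Information gain of a discrete feature about the class
#'
#' `IG(C, F) = H(C) - H(C | F)` with
#' `H(C|F) = sum_f P(F = f) H(C | F = f)`, in bits. Used to score how much a
#' convolving filter's (binarized) pooled output tells about a chapter label.
#'
#' @param feature discrete feature vector (typically binary).
#' @param labels class labels (typically binary, both classes present).
#' @return information gain in bits.
#' @export
information_gain <- function(feature, labels) {
  if (length(feature) != length(labels)) {
    stop("feature and labels differ in length")
  }
  h_c <- entropy_bits(table(labels))
  n <- length(labels)
  h_cond <- 0
  for (f in unique(feature)) {
    sel <- feature == f
    h_cond <- h_cond + sum(sel) / n * entropy_bits(table(labels[sel]))
  }
  h_c - h_cond
}

#' Binarize pooled activations by an IG-maximizing threshold
#'
#' The threshold is chosen on training data among the midpoints of
#' consecutive sorted distinct activation values, maximizing the training
#' information gain (ties broken toward the smallest threshold); it is then
#' applied unchanged to any other activation vector. Constant activations
#' yield an all-zero feature.
#'
#' @param pooled numeric pooled activations (training set).
#' @param labels binary training labels.
#' @return list with `threshold` and `feature` (binary vector,
#'   `pooled > threshold`).
#' @export
binarize_activation <- function(pooled, labels) {
  u <- sort(unique(pooled))
  if (length(u) < 2L) {
    return(list(threshold = u[1], feature = rep(0L, length(pooled))))
  }
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary for binarization")
  n <- length(pooled)
  ord <- order(pooled)
  ps <- pooled[ord]; ys <- y[ord]
  # candidate cut after position i (i obs at/below the threshold), only at
  # boundaries between distinct activation values
  cuts <- which(diff(ps) > 0)
  c1 <- cumsum(ys)                       # positives at/below each position
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  hbin <- function(k1, ktot) {           # entropy of a (k1, ktot-k1) split
    p <- ifelse(ktot > 0, k1 / ktot, 0)
    -(plogp(p) + plogp(1 - p))
  }
  nl <- cuts; n1l <- c1[cuts]
  nr <- n - nl; n1r <- sum(ys) - n1l
  h_cond <- nl / n * hbin(n1l, nl) + nr / n * hbin(n1r, nr)
  ig <- entropy_bits(table(y)) - h_cond
  best_cut <- cuts[which.max(ig)]
  best <- (ps[best_cut] + ps[best_cut + 1L]) / 2
  list(threshold = best, feature = as.integer(pooled > best))
}

#' Per-filter information-gain profiles
#'
#' For every convolving filter of a fitted CNN: binarize its pooled
#' activation on the training notes (IG-maximizing threshold), compute the
#' information gain about the task label on the training set and — with the
#' same threshold — on the test set, and their ratio (capped at 1; undefined
#' when the training IG is below `eps`).
#'
#' @param fit a [note_cnn()] fit.
#' @param x_train,y_train training note matrices and binary labels.
#' @param x_test,y_test optional test set.
#' @param eps training-IG floor below which the ratio is undefined.
#' @return data.frame with one row per filter: `channel`, `filter`, `height`,
#'   `threshold`, `ig_train`, `ig_test`, `ig_ratio`.
#' @export
filter_profiles <- function(fit, x_train, y_train, x_test = NULL,
                            y_test = NULL, eps = 1e-6) {
  pooled_tr <- predict(fit, x_train, type = "pooled")
  pooled_te <- if (!is.null(x_test)) predict(fit, x_test, type = "pooled")
  ch <- fit$channels
  chan_of <- rep(seq_len(nrow(ch)), ch$k)
  filt_of <- unlist(lapply(ch$k, seq_len))
  K <- sum(ch$k)
  out <- data.frame(channel = chan_of, filter = filt_of,
                    height = ch$h[chan_of], threshold = NA_real_,
                    ig_train = NA_real_, ig_test = NA_real_,
                    ig_ratio = NA_real_)
  for (j in seq_len(K)) {
    bin <- binarize_activation(pooled_tr[, j], y_train)
    out$threshold[j] <- bin$threshold
    out$ig_train[j] <- information_gain(bin$feature, y_train)
    if (!is.null(pooled_te) && !is.null(y_test)) {
      fe_te <- as.integer(pooled_te[, j] > bin$threshold)
      out$ig_test[j] <- information_gain(fe_te, y_test)
      if (out$ig_train[j] >= eps) {
        out$ig_ratio[j] <- min(1, out$ig_test[j] / out$ig_train[j])
      }
    }
  }
  out
}

#' Geometric mean of the train/test information-gain ratios
#'
#' Summarises how well the filters' informativeness transfers from training
#' to test data: `exp(mean(log(ratio)))` over filters whose training IG is
#' at least `eps`, ratios capped at 1.
#'
#' @param profiles data.frame from [filter_profiles()] (needs `ig_train`,
#'   `ig_test`), or a numeric vector of ratios.
#' @param eps eligibility floor on the training IG.
#' @return geometric mean in `[0, 1]`, or `NA` (with a warning) when no
#'   filter is eligible.
#' @export
ig_ratio_summary <- function(profiles, eps = 1e-6) {
  if (is.numeric(profiles)) {
    ratios <- pmin(profiles, 1)
  } else {
    ok <- !is.na(profiles$ig_train) & profiles$ig_train >= eps &
      !is.na(profiles$ig_test)
    ratios <- pmin(profiles$ig_test[ok] / profiles$ig_train[ok], 1)
  }
  if (length(ratios) == 0L) {
    warning("no filter with training IG above the floor; ratio undefined")
    return(NA_real_)
  }
  exp(mean(log(pmax(ratios, .Machine$double.xmin))))
}

#' Chance-level information gain of optimized binarization
#'
#' [binarize_activation()] maximizes the training IG over candidate
#' thresholds, so even a label-independent filter shows a small positive
#' "information gain" by overfitting; its magnitude depends on the sample
#' size. This estimates that chance level by rerunning the threshold search
#' against permuted labels and taking an upper quantile of the resulting IGs
#' across filters and permutations. Use it as the eligibility floor
#' (`eps`) when summarizing IG transfer with [ig_ratio_summary()], so that
#' filters indistinguishable from noise do not dominate the geometric mean.
#'
#' @param pooled notes x filters matrix of pooled activations (training
#'   set), e.g. `predict(fit, x, type = "pooled")`.
#' @param labels binary training labels.
#' @param n_perm number of label permutations.
#' @param probs quantile of the null IG distribution to return.
#' @param rng_seed seed for the permutations.
#' @return the IG noise floor in bits.
#' @export
ig_noise_floor <- function(pooled, labels, n_perm = 3L, probs = 0.95,
                           rng_seed = 1L) {
  set.seed(rng_seed)
  null_ig <- replicate(n_perm, {
    yp <- sample(labels)
    vapply(seq_len(ncol(pooled)), function(j) {
      bin <- binarize_activation(pooled[, j], yp)
      information_gain(bin$feature, yp)
    }, numeric(1))
  })
  as.numeric(stats::quantile(null_ig, probs))
}

#' Top-activating n-grams of one convolving filter
#'
#' Scans every height-`h` token window of the corpus, computes the filter's
#' pre-pool ReLU activation, and returns the `k` distinct n-grams with the
#' highest activation, together with the number of notes in which the n-gram
#' is the argmax (pooled) window.
#'
#' @param fit a [note_cnn()] fit.
#' @param channel,filter filter coordinates (channel index, filter index
#'   within channel).
#' @param tokens_list list of token vectors (one per note).
#' @param table the `embedding_table` used to encode the notes.
#' @param k number of n-grams to return.
#' @return data.frame `ngram`, `activation`, `n_argmax`, sorted by
#'   activation; empty when no window activates above zero.
#' @export
top_filter_ngrams <- function(fit, channel, filter, tokens_list, table,
                              k = 10L) {
  ch <- fit$channels
  stopifnot(channel >= 1L, channel <= nrow(ch),
            filter >= 1L, filter <= ch$k[channel])
  h <- ch$h[channel]
  w <- fit$params$W[[channel]][filter, ]
  b <- fit$params$b[[channel]][filter]
  d <- fit$d

  best <- new.env(parent = emptyenv())
  argmax_count <- new.env(parent = emptyenv())
  for (tk in tokens_list) {
    idx <- match(tk, rownames(table$vectors))
    tk <- tk[!is.na(idx)]
    idx <- idx[!is.na(idx)]
    if (length(tk) < h) next
    M <- table$vectors[idx, , drop = FALSE]
    nw <- length(tk) - h + 1L
    act <- rep(b, nw)
    for (o in seq_len(h) - 1L) {
      act <- act + as.numeric(M[(1L + o):(nw + o), , drop = FALSE] %*%
                                w[(o * d + 1L):((o + 1L) * d)])
    }
    act <- pmax(act, 0)
    grams <- vapply(seq_len(nw), function(t) {
      paste(tk[t:(t + h - 1L)], collapse = " ")
    }, character(1))
    for (t in seq_len(nw)) {
      g <- grams[t]
      cur <- get0(g, envir = best, ifnotfound = -Inf)
      if (act[t] > cur) assign(g, act[t], envir = best)
    }
    if (any(act > 0)) {
      am <- grams[which.max(act)]
      assign(am, get0(am, envir = argmax_count, ifnotfound = 0L) + 1L,
             envir = argmax_count)
    }
  }
  grams <- ls(best)
  if (length(grams) == 0L) {
    return(data.frame(ngram = character(0), activation = numeric(0),
                      n_argmax = integer(0)))
  }
  act <- vapply(grams, get, numeric(1), envir = best)
  keep <- act > 0
  grams <- grams[keep]; act <- act[keep]
  if (length(grams) == 0L) {
    return(data.frame(ngram = character(0), activation = numeric(0),
                      n_argmax = integer(0)))
  }
  ord <- order(-act, grams)
  take <- seq_len(min(k, length(grams)))
  grams <- grams[ord][take]; act <- act[ord][take]
  n_am <- vapply(grams, function(g) {
    get0(g, envir = argmax_count, ifnotfound = 0L)
  }, integer(1))
  data.frame(ngram = grams, activation = act, n_argmax = n_am,
             row.names = NULL)
}

#' Write a filter-analysis report
#'
#' JSON report per task: one record per filter with its IG statistics and,
#' for the most informative filters, the top-activating n-grams.
#'
#' @param profiles data.frame from [filter_profiles()].
#' @param path output JSON path.
#' @param top_ngrams optional named list (filter label -> data.frame from
#'   [top_filter_ngrams()]).
#' @export
write_filter_report <- function(profiles, path, top_ngrams = NULL) {
  obj <- list(filters = profiles,
              ig_ratio_geometric_mean = ig_ratio_summary(profiles))
  if (!is.null(top_ngrams)) obj$top_ngrams <- top_ngrams
  jsonlite::write_json(obj, path, digits = NA, dataframe = "rows",
                       auto_unbox = TRUE)
  invisible(path)
}

#' Plot the information-gain distribution of the filters
#'
#' @param profiles data.frame from [filter_profiles()].
#' @param ... passed to [graphics::boxplot()].
#' @export
plot_filter_ig <- function(profiles, ...) {
  graphics::boxplot(list(train = profiles$ig_train,
                         test = profiles$ig_test[!is.na(profiles$ig_test)]),
                    ylab = "information gain (bits)",
                    main = "Convolving-filter information gain", ...)
  invisible(profiles)
}
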