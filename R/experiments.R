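#' Concept-recovery experiment
#'
#' Trains the CNN on one planted label of a synthetic corpus, profiles every
#' convolving filter's information gain on the training notes, and checks
#' whether the top-IG filter's top-activating n-grams contain at least one
#' of the label's planted signal words — the synthetic analogue of
#' inspecting a trained filter and finding it fires on concept keywords.
#'
#' @param spec a [corpus_spec()]; one run per seed offset.
#' @param label index of the planted label to train on.
#' @param config CNN [training_config()].
#' @param top_k how many top n-grams of the top filter to inspect.
#' @return list with `recovered` (logical), `top_filter` (row of the filter
#'   profile), `top_ngrams` (data.frame) and `signal_words`.
#' @export
concept_recovery_experiment <- function(spec, label = 1L,
                                        config = training_config(),
                                        top_k = 10L) {
  tab <- generate_embeddings(spec)
  corp <- generate_corpus(spec, tab)
  tokens <- tokenize(corp$text)
  y <- as.numeric(attr(corp, "labels")[, label])
  enc <- encode_corpus(tokens, tab)
  os <- oversample(y, rng_seed = config$rng_seed)
  fit <- note_cnn(enc[os], y[os], config = config)
  prof <- filter_profiles(fit, enc, y)
  top <- prof[which.max(prof$ig_train), ]
  ng <- top_filter_ngrams(fit, top$channel, top$filter, tokens, tab,
                          k = top_k)
  sig <- attr(corp, "signal_words")[[label]]
  hit_tokens <- unique(unlist(strsplit(ng$ngram, " ", fixed = TRUE)))
  list(recovered = any(hit_tokens %in% sig), top_filter = top,
       top_ngrams = ng, signal_words = sig)
}

#' Emerging-synonym experiment
#'
#' The deployment scenario in which a disease term enters use only after the
#' training period (as H1N1 did for influenza): with
#' `emerging_fraction > 0`, part of each label's signal words is reserved
#' for post-cutoff notes. Trains the CNN and the bag-of-words linear SVM on
#' the pre-cutoff notes and compares their AUC on the post-cutoff notes
#' whose positive-label signal tokens are exclusively reserved words
#' (together with all post-cutoff negatives). The reserved words have zero
#' training-corpus counts, so the term-count model cannot score them, while
#' their embeddings lie near the trained concept cluster.
#'
#' @param spec a [corpus_spec()] with `emerging_fraction > 0`.
#' @param config CNN [training_config()].
#' @param seed master seed for oversampling and model fits.
#' @return list with `per_task` (data.frame: task, n_reserved_pos, cnn_auc,
#'   svm_auc), `cnn_auc`, `svm_auc` (means over evaluable tasks) and `gap`.
#' @export
emerging_synonym_experiment <- function(spec,
                                        config = training_config(),
                                        seed = 1L) {
  if (spec$emerging_fraction <= 0) {
    stop("spec must reserve emerging signal words (emerging_fraction > 0)")
  }
  tab <- generate_embeddings(spec)
  corp <- generate_corpus(spec, tab)
  tokens <- tokenize(corp$text)
  labels <- attr(corp, "labels")
  signal <- attr(corp, "signal_words")
  emerging <- attr(corp, "emerging_words")
  chapters <- attr(corp, "label_chapters")
  sp <- split_temporal(corp$date, spec$cutoff_date)
  enc <- encode_corpus(tokens, tab)
  feats <- corpus_features(tokens[sp$train])
  dtm_tr <- build_document_term_matrix(tokens[sp$train], feats)
  dtm_te <- build_document_term_matrix(tokens[sp$test], feats)

  rows <- lapply(seq_len(spec$n_labels), function(l) {
    y_tr <- as.numeric(labels[sp$train, l])
    y_te <- as.numeric(labels[sp$test, l])
    old <- setdiff(signal[[l]], emerging[[l]])
    res_pos <- vapply(seq_along(sp$test), function(i) {
      tk <- tokens[[sp$test[i]]]
      y_te[i] == 1 && any(tk %in% emerging[[l]]) && !any(tk %in% old)
    }, logical(1))
    keep <- which(res_pos | y_te == 0)
    out <- data.frame(task = chapters[l], n_reserved_pos = sum(res_pos),
                      cnn_auc = NA_real_, svm_auc = NA_real_)
    if (sum(res_pos) < 2L || length(unique(y_tr)) < 2L) return(out)
    task_seed <- (seed * 1009L + l * 7L) %% 2147483647L
    os <- oversample(y_tr, rng_seed = task_seed)
    cfg <- config; cfg$rng_seed <- task_seed
    fit <- note_cnn(enc[sp$train][os], y_tr[os], config = cfg)
    svm <- train_baseline("svm_linear", dtm_tr[os, , drop = FALSE],
                          y_tr[os], seed = task_seed)
    y_sub <- y_te[keep]
    out$cnn_auc <- roc_auc(predict(fit, enc[sp$test][keep]), y_sub)
    out$svm_auc <- roc_auc(score_baseline(svm, dtm_te[keep, , drop = FALSE]),
                           y_sub)
    out
  })
  per_task <- do.call(rbind, rows)
  ok <- !is.na(per_task$cnn_auc)
  list(per_task = per_task,
       cnn_auc = mean(per_task$cnn_auc[ok]),
       svm_auc = mean(per_task$svm_auc[ok]),
       gap = mean(per_task$cnn_auc[ok]) - mean(per_task$svm_auc[ok]))
}
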