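#' Evaluate a pipeline on a note corpus
#'
#' Runs the full one-vs-rest protocol for one model family: derive chapter
#' labels from the codes field, split (5-fold cross-validation or a
#' date-based train/test split), oversample each training part to class
#' balance, train one binary model per chapter task, score, and compute
#' training and test AUC and F-measure per task. Cross-validation rows are
#' fold averages.
#'
#' @param notes note table (data.frame `id`, `date`, `text`, `codes`), see
#'   [read_notes()].
#' @param model `"cnn"` or a baseline kind (see [train_baseline()]).
#' @param mode `"cv5"` (k-fold cross-validation) or `"temporal"`.
#' @param embeddings an `embedding_table`; required for the CNN.
#' @param k number of CV folds.
#' @param cutoff cutoff date for `mode = "temporal"`.
#' @param tasks chapter identifiers to evaluate; default: all chapters
#'   present in the corpus.
#' @param channels,config CNN geometry and training hyperparameters.
#' @param dictionary optional synonym dictionary for the baseline features.
#' @param ngram_min_count n-gram corpus-count filter (strictly greater
#'   than) for the baseline vocabulary.
#' @param min_rows minimum encoded note height (CNN).
#' @param f_threshold decision threshold for the F-measure; default 0.5 for
#'   probability models and 0 for SVM decision values.
#' @param seed master seed: all fold/task-level seeds derive from it.
#' @return an `icd_eval` report (see [summarize_eval()]); its `rows` carry
#'   `model`, `task`, `train_auc`, `test_auc`, `train_f`, `test_f`. Tasks
#'   with a single class in a split are reported as `NA` and skipped in
#'   aggregates.
#' @export
evaluate_pipeline <- function(notes, model = "cnn",
                              mode = c("cv5", "temporal"),
                              embeddings = NULL, k = 5L,
                              cutoff = as.Date("2016-07-01"), tasks = NULL,
                              channels = channel_spec(),
                              config = training_config(),
                              dictionary = NULL, ngram_min_count = 10L,
                              min_rows = 5L, f_threshold = NULL,
                              seed = 1L) {
  mode <- match.arg(mode)
  tokens <- tokenize(notes$text)
  chap <- note_chapters(notes$codes)
  if (is.null(tasks)) tasks <- sort(unique(unlist(chap)))
  if (length(tasks) == 0L) stop("no chapter task present in the corpus")
  Y <- vapply(tasks, function(ta) {
    vapply(chap, function(cc) ta %in% cc, logical(1))
  }, logical(length(chap)))
  Y <- matrix(as.numeric(Y), nrow = length(chap),
              dimnames = list(NULL, tasks))
  n <- nrow(notes)
  is_cnn <- identical(model, "cnn")
  if (is.null(f_threshold)) {
    f_threshold <- if (!is_cnn && startsWith(model, "svm")) 0 else 0.5
  }
  if (is_cnn && is.null(embeddings)) stop("the CNN needs an embedding table")

  splits <- if (mode == "cv5") {
    split_kfold(n, k, rng_seed = seed)
  } else {
    list(split_temporal(notes$date, cutoff))
  }

  enc <- NULL
  if (is_cnn) {
    enc <- encode_corpus(tokens, embeddings,
                         min_rows = max(min_rows, max(channels$h)))
  }

  per_fold <- vector("list", length(splits))
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    if (length(sp$train) == 0L || length(sp$test) == 0L) {
      stop("empty split side; cannot evaluate")
    }
    dtm_tr <- dtm_te <- NULL
    if (!is_cnn) {
      tr_tokens <- apply_synonyms(tokens[sp$train], dictionary)
      feats <- corpus_features(tokens[sp$train],
                               min_count_exclusive = ngram_min_count,
                               dictionary = dictionary)
      dtm_tr <- build_document_term_matrix(tr_tokens, feats)
      dtm_te <- build_document_term_matrix(
        apply_synonyms(tokens[sp$test], dictionary), feats)
    }
    rows <- lapply(seq_along(tasks), function(ti) {
      y_tr <- Y[sp$train, ti]; y_te <- Y[sp$test, ti]
      out <- data.frame(model = model, task = tasks[ti],
                        train_auc = NA_real_, test_auc = NA_real_,
                        train_f = NA_real_, test_f = NA_real_)
      if (length(unique(y_tr)) < 2L) return(out)
      task_seed <- (seed * 1009L + s * 131L + ti * 7L) %% 2147483647L
      os <- oversample(y_tr, rng_seed = task_seed)
      sc_tr <- sc_te <- NULL
      if (is_cnn) {
        cfg <- config; cfg$rng_seed <- task_seed
        fit <- note_cnn(enc[sp$train][os], y_tr[os], channels = channels,
                        config = cfg)
        sc_tr <- predict(fit, enc[sp$train])
        sc_te <- predict(fit, enc[sp$test])
      } else {
        fit <- train_baseline(model, dtm_tr[os, , drop = FALSE], y_tr[os],
                              seed = task_seed)
        sc_tr <- score_baseline(fit, dtm_tr)
        sc_te <- score_baseline(fit, dtm_te)
      }
      out$train_auc <- roc_auc(sc_tr, y_tr)
      out$train_f <- f_measure(sc_tr, y_tr, f_threshold)[["f"]]
      if (length(unique(y_te)) >= 2L) {
        out$test_auc <- roc_auc(sc_te, y_te)
        out$test_f <- f_measure(sc_te, y_te, f_threshold)[["f"]]
      }
      out
    })
    per_fold[[s]] <- do.call(rbind, rows)
  }
  rows <- do.call(rbind, lapply(seq_along(tasks), function(ti) {
    fold_rows <- do.call(rbind, lapply(per_fold, function(fr) fr[ti, ]))
    data.frame(model = model, task = tasks[ti],
               train_auc = mean(fold_rows$train_auc, na.rm = TRUE),
               test_auc = mean(fold_rows$test_auc, na.rm = TRUE),
               train_f = mean(fold_rows$train_f, na.rm = TRUE),
               test_f = mean(fold_rows$test_f, na.rm = TRUE))
  }))
  rows[is.na(rows)] <- NA  # NaN from all-NA means
  summarize_eval(rows)
}

#' Run configuration for the end-to-end pipeline
#'
#' Defaults reproduce the reference protocol: 5 cross-validation folds, a
#' 2016-07-01 deployment cutoff for the temporal mode, and the reference CNN
#' hyperparameters.
#'
#' @param notes_path path to the note table (TSV, see [read_notes()]).
#' @param vectors_path path to the word-vector text file.
#' @param out_dir output directory for reports and artifacts.
#' @param model pipeline selection: `"cnn"` or a baseline kind.
#' @param mode `"cv5"` or `"temporal"`.
#' @param k CV folds.
#' @param cutoff cutoff date (ISO-8601) for temporal mode.
#' @param config a [training_config()].
#' @param channels a [channel_spec()].
#' @param seed master seed.
#' @param filter_report write the convolving-filter IG report (CNN +
#'   temporal mode only)?
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(notes_path, vectors_path = NULL, out_dir = "run",
                       model = "cnn", mode = "cv5", k = 5L,
                       cutoff = "2016-07-01", config = training_config(),
                       channels = channel_spec(), seed = 1L,
                       filter_report = TRUE) {
  if (!mode %in% c("cv5", "temporal")) {
    stop("field 'mode' must be \"cv5\" or \"temporal\"")
  }
  cutoff_d <- tryCatch(as.Date(cutoff), error = function(e) NA)
  if (is.na(cutoff_d)) stop("field 'cutoff' is not a valid ISO-8601 date: ", cutoff)
  structure(list(notes_path = notes_path, vectors_path = vectors_path,
                 out_dir = out_dir, model = model, mode = mode,
                 k = as.integer(k), cutoff = cutoff_d, config = config,
                 channels = channels, seed = as.integer(seed),
                 filter_report = isTRUE(filter_report)),
            class = "run_config")
}

#' Run the end-to-end pipeline and write artifacts
#'
#' Reads the inputs, evaluates the selected pipeline, and writes under the
#' run directory: `report.tsv` (per-task rows), `summary.json` (aggregates),
#' `manifest.json` (configuration and seeds), and for a temporal CNN run a
#' model checkpoint and the convolving-filter information-gain report.
#'
#' @param rc a [run_config()].
#' @return the `icd_eval` report, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  if (!file.exists(rc$notes_path)) stop("notes file not found: ", rc$notes_path)
  if (identical(rc$model, "cnn")) {
    if (is.null(rc$vectors_path) || !file.exists(rc$vectors_path)) {
      stop("word-vector file not found: ", rc$vectors_path)
    }
  }
  notes <- read_notes(rc$notes_path)
  table <- if (!is.null(rc$vectors_path)) load_word_vectors(rc$vectors_path)
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)

  report <- evaluate_pipeline(notes, model = rc$model, mode = rc$mode,
                              embeddings = table, k = rc$k,
                              cutoff = rc$cutoff, channels = rc$channels,
                              config = rc$config, seed = rc$seed)
  write_eval(report, file.path(rc$out_dir, "report.tsv"),
             file.path(rc$out_dir, "summary.json"))

  manifest <- list(model = rc$model, mode = rc$mode, k = rc$k,
                   cutoff = format(rc$cutoff), seed = rc$seed,
                   config = unclass(rc$config),
                   channels = rc$channels,
                   notes = rc$notes_path, vectors = rc$vectors_path,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(rc$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  if (identical(rc$model, "cnn") && rc$mode == "temporal" &&
      rc$filter_report) {
    tokens <- tokenize(notes$text)
    chapset <- note_chapters(notes$codes)
    tasks <- sort(unique(unlist(chapset)))
    enc <- encode_corpus(tokens, table,
                         min_rows = max(5L, max(rc$channels$h)))
    sp <- split_temporal(notes$date, rc$cutoff)
    for (ta in tasks) {
      y <- vapply(chapset, function(cc) as.numeric(ta %in% cc), numeric(1))
      if (length(unique(y[sp$train])) < 2L) next
      cfg <- rc$config
      cfg$rng_seed <- (rc$seed * 1009L + match(ta, tasks) * 7L) %% 2147483647L
      os <- oversample(y[sp$train], rng_seed = cfg$rng_seed)
      fit <- note_cnn(enc[sp$train][os], y[sp$train][os],
                      channels = rc$channels, config = cfg)
      write_cnn(fit, file.path(rc$out_dir, paste0("cnn_", ta, ".json")))
      prof <- filter_profiles(fit, enc[sp$train], y[sp$train],
                              enc[sp$test],
                              if (length(unique(y[sp$test])) >= 2L)
                                y[sp$test] else NULL)
      write_filter_report(prof,
                          file.path(rc$out_dir,
                                    paste0("filters_", ta, ".json")))
    }
  }
  invisible(report)
}
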