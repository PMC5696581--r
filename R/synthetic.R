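#' Specification of a synthetic discharge-note corpus
#'
#' Describes a corpus with the statistical structure the classifier exploits:
#' each label (chapter) owns a concept cluster in embedding space; positive
#' notes inject that label's signal words among Zipf-distributed background
#' tokens; labels are assigned independently with chapter-specific
#' prevalences; notes carry dates, and a share of each label's signal words
#' can be reserved for post-cutoff notes only (the emerging-synonym
#' scenario: terms unseen in training whose embeddings lie near seen concept
#' words).
#'
#' @param n_notes number of notes.
#' @param n_labels number of label concepts (mapped to ICD-10-CM chapters).
#' @param prevalences per-label marginal prevalence in `(0, 1)`; the default
#'   mirrors the spread of chapter prevalences seen in hospital discharge
#'   data (common chapters around a third of notes, rare ones a few percent).
#' @param signal_words_per_label number of signal (synonym) words per label.
#' @param p_signal probability that a positive note contains each eligible
#'   signal word of its label.
#' @param background_vocab number of background words.
#' @param note_length integer range `c(min, max)` of tokens per note.
#' @param date_range corpus date span `c(first, last)`.
#' @param cutoff_date the deployment cutoff separating training-period from
#'   test-period notes.
#' @param emerging_fraction share of each label's signal words reserved for
#'   post-cutoff notes; reserved words never occur before the cutoff. A
#'   post-cutoff positive note expresses its label through the reserved
#'   synonym set with this probability (an "emerging presentation"),
#'   otherwise through the training-period set.
#' @param d embedding dimension.
#' @param sigma concept cluster spread: signal-word vectors are their
#'   label's unit center plus isotropic Gaussian noise with this sd.
#' @param zipf_exponent exponent of the Zipf law for background word
#'   frequencies.
#' @param rng_seed seed; generation is deterministic given the spec.
#' @return a list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_notes = 2000L, n_labels = 6L,
                        prevalences = NULL,
                        signal_words_per_label = 12L, p_signal = 0.25,
                        background_vocab = 500L, note_length = c(15L, 40L),
                        date_range = c("2016-01-01", "2016-12-31"),
                        cutoff_date = "2016-07-01",
                        emerging_fraction = 0, d = 20L, sigma = 0.1,
                        zipf_exponent = 1.1, rng_seed = 1L) {
  if (is.null(prevalences)) {
    base <- c(0.335, 0.282, 0.213, 0.130, 0.074, 0.037)
    prevalences <- rep_len(base, n_labels)
  }
  stopifnot(n_notes >= 1L, n_labels >= 1L,
            length(prevalences) == n_labels,
            all(prevalences > 0), all(prevalences < 1),
            signal_words_per_label >= 1L, p_signal >= 0, p_signal <= 1,
            background_vocab >= 1L, length(note_length) == 2L,
            note_length[1] >= 1L, note_length[2] >= note_length[1],
            emerging_fraction >= 0, emerging_fraction < 1,
            d >= 2L, sigma > 0)
  if (n_labels > 21L) stop("at most 21 labels (one per ICD-10-CM chapter)")
  structure(list(n_notes = as.integer(n_notes),
                 n_labels = as.integer(n_labels),
                 prevalences = prevalences,
                 signal_words_per_label = as.integer(signal_words_per_label),
                 p_signal = p_signal,
                 background_vocab = as.integer(background_vocab),
                 note_length = as.integer(note_length),
                 date_range = as.Date(date_range),
                 cutoff_date = as.Date(cutoff_date),
                 emerging_fraction = emerging_fraction,
                 d = as.integer(d), sigma = sigma,
                 zipf_exponent = zipf_exponent,
                 rng_seed = as.integer(rng_seed)),
            class = "corpus_spec")
}

#' The packaged "small" corpus spec
#'
#' The default conditions used throughout the test suite: 2000 notes, 6
#' labels, 20-dimensional embeddings, cluster spread 0.1.
#'
#' @param rng_seed seed.
#' @param ... overrides passed to [corpus_spec()].
#' @export
small_corpus_spec <- function(rng_seed = 1L, ...) {
  args <- list(n_notes = 2000L, n_labels = 6L, d = 20L, sigma = 0.1,
               rng_seed = rng_seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(corpus_spec, args)
}

# chapters used for synthetic labels, most common first (mirrors the rank
# order seen in hospital data)
.synthetic_chapters <- function(n_labels) {
  pref <- c("C00-D49", "I00-I99", "E00-E89", "J00-J99", "D50-D89", "O00-O9A")
  all21 <- icd10_chapters()$chapter
  out <- c(pref, setdiff(all21, pref))[seq_len(n_labels)]
  out
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Generate concept-clustered word embeddings
#'
#' One unit-norm cluster center per label; signal words (including reserved
#' "emerging" ones) are their center plus Gaussian noise of sd `sigma`;
#' background words are unit vectors resampled until they are far (absolute
#' cosine < 0.5) from every center.
#'
#' @param spec a [corpus_spec()].
#' @return an `embedding_table` whose attributes `signal_words`,
#'   `emerging_words` (lists, one character vector per label) and
#'   `label_chapters` describe the planted structure.
#' @export
generate_embeddings <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$rng_seed)
  L <- spec$n_labels; d <- spec$d; s <- spec$signal_words_per_label
  centers <- matrix(0, L, d)
  for (l in seq_len(L)) {
    for (try in 1:1000) {
      v <- .unit(stats::rnorm(d))
      if (l == 1L || max(abs(centers[seq_len(l - 1L), , drop = FALSE] %*% v)) < 0.5) {
        centers[l, ] <- v
        break
      }
    }
    if (all(centers[l, ] == 0)) stop("could not place separated cluster centers")
  }
  n_emerging <- round(spec$emerging_fraction * s)
  signal <- lapply(seq_len(L), function(l) sprintf("sig%dw%d", l, seq_len(s)))
  emerging <- lapply(seq_len(L), function(l) {
    if (n_emerging > 0) signal[[l]][(s - n_emerging + 1L):s] else character(0)
  })
  sig_vecs <- do.call(rbind, lapply(seq_len(L), function(l) {
    t(vapply(seq_len(s), function(j) {
      centers[l, ] + stats::rnorm(d, 0, spec$sigma)
    }, numeric(d)))
  }))
  rownames(sig_vecs) <- unlist(signal)
  B <- spec$background_vocab
  bg_vecs <- matrix(0, B, d)
  for (i in seq_len(B)) {
    for (try in 1:1000) {
      v <- .unit(stats::rnorm(d))
      if (max(abs(centers %*% v)) < 0.5) { bg_vecs[i, ] <- v; break }
    }
    if (all(bg_vecs[i, ] == 0)) stop("could not place background word vectors")
  }
  rownames(bg_vecs) <- sprintf("bg%d", seq_len(B))
  tab <- structure(list(d = d, vectors = rbind(sig_vecs, bg_vecs)),
                   class = "embedding_table")
  attr(tab, "signal_words") <- signal
  attr(tab, "emerging_words") <- emerging
  attr(tab, "label_chapters") <- .synthetic_chapters(L)
  attr(tab, "centers") <- centers
  tab
}

#' Generate a synthetic discharge-note corpus
#'
#' Each note draws every label independently with its prevalence; a positive
#' label injects each of its eligible signal words with probability
#' `p_signal` into a background of Zipf-sampled tokens; token order is
#' random. Dates are uniform over the date range; signal words reserved as
#' "emerging" (see [corpus_spec()]) never occur in notes dated before the
#' cutoff. Each note's codes field carries one representative ICD-10-CM code
#' per positive label, so chapter ground truth round-trips through
#' [note_chapters()].
#'
#' @param spec a [corpus_spec()].
#' @param table the matching table from [generate_embeddings()].
#' @return data.frame with columns `id`, `date`, `text`, `codes`, plus
#'   attributes `labels` (n x L logical matrix), `label_chapters`,
#'   `signal_words`, `emerging_words`.
#' @export
generate_corpus <- function(spec, table = generate_embeddings(spec)) {
  stopifnot(inherits(spec, "corpus_spec"), inherits(table, "embedding_table"))
  signal <- attr(table, "signal_words")
  emerging <- attr(table, "emerging_words")
  chapters <- attr(table, "label_chapters")
  if (is.null(signal)) stop("table does not carry the planted-structure attributes")
  L <- spec$n_labels
  set.seed(spec$rng_seed + 1L)

  B <- spec$background_vocab
  zipf <- (1 / seq_len(B))^spec$zipf_exponent
  zipf <- zipf / sum(zipf)
  bg_words <- sprintf("bg%d", seq_len(B))

  n <- spec$n_notes
  days <- seq(spec$date_range[1], spec$date_range[2], by = "day")
  dates <- sample(days, n, replace = TRUE)
  lab <- matrix(stats::rbinom(n * L, 1L, rep(spec$prevalences, each = n)),
                n, L) == 1L
  texts <- character(n)
  for (i in seq_len(n)) {
    len <- sample(spec$note_length[1]:spec$note_length[2], 1L)
    sig_tokens <- character(0)
    for (l in which(lab[i, ])) {
      old <- setdiff(signal[[l]], emerging[[l]])
      eligible <- if (dates[i] < spec$cutoff_date) {
        old
      } else if (spec$emerging_fraction > 0 &&
                 length(emerging[[l]]) > 0 &&
                 stats::runif(1) < spec$emerging_fraction) {
        emerging[[l]]
      } else {
        if (dates[i] >= spec$cutoff_date && spec$emerging_fraction == 0)
          signal[[l]] else old
      }
      if (length(eligible) == 0L) next
      take <- eligible[stats::runif(length(eligible)) < spec$p_signal]
      sig_tokens <- c(sig_tokens, take)
    }
    n_bg <- max(len - length(sig_tokens), 3L)
    toks <- c(sample(bg_words, n_bg, replace = TRUE, prob = zipf), sig_tokens)
    texts[i] <- paste(sample(toks), collapse = " ")
  }
  codes <- vapply(seq_len(n), function(i) {
    ch <- chapters[lab[i, ]]
    paste(substr(ch, 1, 3), collapse = ";")
  }, character(1))
  out <- data.frame(id = sprintf("note%05d", seq_len(n)),
                    date = dates, text = texts, codes = codes,
                    stringsAsFactors = FALSE)
  attr(out, "labels") <- lab
  attr(out, "label_chapters") <- chapters
  attr(out, "signal_words") <- signal
  attr(out, "emerging_words") <- emerging
  out
}
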