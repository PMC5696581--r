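# Enumerate all contiguous n-grams of one token vector for n in [n_min, n_max],
# joined with single spaces. Order of enumeration is by n then position.
.ngrams_of <- function(tokens, n_min, n_max) {
  L <- length(tokens)
  out <- vector("list", max(0L, n_max - n_min + 1L))
  j <- 0L
  for (n in n_min:n_max) {
    if (n > L) break
    j <- j + 1L
    if (n == 1L) {
      out[[j]] <- tokens
    } else {
      m <- vapply(seq_len(L - n + 1L), function(t) {
        paste(tokens[t:(t + n - 1L)], collapse = " ")
      }, character(1))
      out[[j]] <- m
    }
  }
  unlist(out, use.names = FALSE)
}

#' Extract frequent n-gram phrase features from a corpus
#'
#' Enumerates all contiguous token n-grams with `n` in `[n_min, n_max]` and
#' keeps those whose total corpus count is strictly greater than
#' `min_count_exclusive` (the count filter reduces feature-space size; it is
#' conventionally applied to phrases only, with unigrams kept unfiltered —
#' see [corpus_features()]).
#'
#' @param tokens list of token vectors (one per note).
#' @param n_min,n_max n-gram length range (defaults 2-5).
#' @param min_count_exclusive keep n-grams with corpus count strictly greater
#'   than this (default 10).
#' @return character vector of n-gram features (space-joined), sorted.
#' @export
extract_ngrams <- function(tokens, n_min = 2L, n_max = 5L,
                           min_count_exclusive = 10L) {
  stopifnot(n_min >= 1L, n_min <= n_max, min_count_exclusive >= 0L)
  if (length(tokens) == 0L) return(character(0))
  all_ng <- unlist(lapply(tokens, .ngrams_of, n_min = n_min, n_max = n_max),
                   use.names = FALSE)
  if (is.null(all_ng) || length(all_ng) == 0L) return(character(0))
  tab <- table(all_ng)
  sort(names(tab)[tab > min_count_exclusive])
}

#' Assemble the bag-of-words feature set of a corpus
#'
#' The feature vocabulary used by the classical baselines: every corpus token
#' as a unigram feature, n-gram phrases (n in 2-5) with corpus count > 10,
#' and - when a synonym dictionary is supplied - `cat:<category>` tokens for
#' dictionary terms occurring in the corpus.
#'
#' @inheritParams extract_ngrams
#' @param dictionary optional named character vector (term -> category), see
#'   [toy_synonym_dictionary()].
#' @return character vector of features (sorted, unique).
#' @export
corpus_features <- function(tokens, n_min = 2L, n_max = 5L,
                            min_count_exclusive = 10L, dictionary = NULL) {
  uni <- sort(unique(unlist(tokens, use.names = FALSE)))
  ng <- if (n_max >= max(2L, n_min)) {
    extract_ngrams(tokens, max(2L, n_min), n_max, min_count_exclusive)
  } else character(0)
  cats <- character(0)
  if (!is.null(dictionary)) {
    hit <- unique(dictionary[names(dictionary) %in% uni])
    if (length(hit)) cats <- paste0("cat:", sort(unname(hit)))
  }
  unique(c(uni, ng, cats))
}

#' Build a document-term matrix
#'
#' Counts occurrences of each feature (unigram or space-joined n-gram) in each
#' note. Feature order is exactly the order of `features`, so matrices built
#' for a test set with the training vocabulary are column-compatible.
#'
#' @param tokens list of token vectors, one per note (after any synonym
#'   expansion, see [apply_synonyms()]).
#' @param features character vector of features; must be nonempty.
#' @return a sparse [Matrix::sparseMatrix] (notes x features, integer counts)
#'   with `features` as column names.
#' @export
build_document_term_matrix <- function(tokens, features) {
  if (length(features) == 0L) stop("feature vocabulary is empty")
  if (anyDuplicated(features)) stop("feature vocabulary has duplicates")
  n_note <- length(tokens)
  lens <- lengths(regmatches(features, gregexpr(" ", features, fixed = TRUE))) + 1L
  n_min <- min(lens)
  n_max <- max(lens)
  ng_by_note <- lapply(tokens, .ngrams_of, n_min = n_min, n_max = n_max)
  all_ng <- unlist(ng_by_note, use.names = FALSE)
  note_id <- rep.int(seq_len(n_note), lengths(ng_by_note))
  j <- match(all_ng, features)
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = note_id[keep], j = j[keep], x = 1,
                       dims = c(n_note, length(features)),
                       dimnames = list(NULL, features))
}
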