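#' Load word vectors from whitespace text format
#'
#' Reads the plain-text word-vector format used by published pretrained
#' embedding releases: one line per token, the token followed by `d` floats,
#' whitespace-separated, UTF-8. The dimension is inferred from the first line
#' and every line must agree.
#'
#' @param path file path.
#' @param expected_dim if given, error unless the file's dimension equals it.
#' @return an `embedding_table`: a list with `d` (integer) and `vectors`
#'   (numeric matrix, one row per token, tokens as rownames).
#' @export
load_word_vectors <- function(path, expected_dim = NULL) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("word-vector file is empty: ", path)
  parts <- strsplit(lines, "[ \t]+")
  nfield <- lengths(parts)
  d <- nfield[1] - 1L
  if (d < 1L) stop("word-vector file line 1 has no vector components")
  bad <- which(nfield != nfield[1])
  if (length(bad)) {
    stop("ragged word-vector file: line ", bad[1], " has ", nfield[bad[1]] - 1L,
         " components, expected ", d)
  }
  if (!is.null(expected_dim) && d != expected_dim) {
    stop("word-vector dimension is ", d, ", expected ", expected_dim)
  }
  toks <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(toks)) stop("duplicate tokens in word-vector file")
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[-1L]), numeric(d)))
  if (anyNA(vals)) stop("non-numeric vector component in word-vector file")
  vecs <- t(matrix(vals, nrow = d))
  rownames(vecs) <- toks
  structure(list(d = as.integer(d), vectors = vecs),
            class = "embedding_table")
}

#' @rdname load_word_vectors
#' @param table an `embedding_table`.
#' @export
write_word_vectors <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  v <- table$vectors
  lines <- paste(rownames(v),
                 apply(v, 1, function(r) paste(format(r, digits = 17,
                                                      scientific = FALSE,
                                                      trim = TRUE),
                                               collapse = " ")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("Word-embedding table:", nrow(x$vectors), "tokens, dimension", x$d, "\n")
  invisible(x)
}

#' Encode a note as an embedding matrix
#'
#' Stacks the embedding vectors of the note's in-vocabulary tokens into an
#' `n x d` matrix, preserving token order. Out-of-vocabulary tokens are
#' dropped (not zero-filled), so convolution windows always span consecutive
#' known words. If fewer than `min_rows` rows remain the matrix is padded at
#' the bottom with zero rows, guaranteeing at least one window for the
#' tallest convolution filter.
#'
#' @param tokens character vector: one note's token sequence.
#' @param table an `embedding_table` from [load_word_vectors()].
#' @param min_rows minimum row count after padding; defaults to 5, the
#'   largest filter height.
#' @return numeric matrix with attributes `n_effective` (non-pad row count),
#'   `tokens` (the retained tokens) and `all_pad` (`TRUE` when no token was in
#'   vocabulary, in which case a warning is raised).
#' @export
encode_note <- function(tokens, table, min_rows = 5L) {
  stopifnot(inherits(table, "embedding_table"), min_rows >= 1L)
  idx <- match(tokens, rownames(table$vectors))
  keep <- which(!is.na(idx))
  m <- table$vectors[idx[keep], , drop = FALSE]
  n_eff <- nrow(m)
  if (n_eff == 0L) warning("note has no in-vocabulary token; all-pad matrix")
  if (n_eff < min_rows) {
    m <- rbind(m, matrix(0, min_rows - n_eff, table$d))
  }
  dimnames(m) <- NULL
  structure(m, n_effective = n_eff, tokens = tokens[keep],
            all_pad = n_eff == 0L)
}

#' Encode every note of a corpus
#'
#' @param tokens_list list of token vectors.
#' @inheritParams encode_note
#' @param quiet suppress the per-note all-pad warnings (a single summary
#'   message is given instead).
#' @return list of note matrices (see [encode_note()]).
#' @export
encode_corpus <- function(tokens_list, table, min_rows = 5L, quiet = TRUE) {
  enc <- if (quiet) {
    out <- suppressWarnings(lapply(tokens_list, encode_note, table = table,
                                   min_rows = min_rows))
    n_pad <- sum(vapply(out, attr, logical(1), "all_pad"))
    if (n_pad > 0) message(n_pad, " note(s) had no in-vocabulary token")
    out
  } else {
    lapply(tokens_list, encode_note, table = table, min_rows = min_rows)
  }
  enc
}

#' Cosine similarity between two vectors
#'
#' @param u,v numeric vectors of equal length, neither all-zero.
#' @return `u . v / (|u| |v|)`, in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1))
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}
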