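#' Tokenize free-text discharge notes
#'
#' Lowercases, splits on every non-alphanumeric character and drops empty
#' pieces. Digit-containing tokens such as `"h1n1"` survive intact, which
#' matters for emerging-disease terms.
#'
#' @param text character vector of raw note texts.
#' @return list of character vectors (one token sequence per text).
#' @export
#' @examples
#' tokenize("Acute MI, s/p PCI.")
tokenize <- function(text) {
  pieces <- strsplit(tolower(as.character(text)), "[^a-z0-9]+")
  out <- lapply(pieces, function(p) p[nzchar(p)])
  # strsplit maps NA to NA; treat as empty text
  out[is.na(text)] <- list(character(0))
  out
}

#' Read and write note tables
#'
#' A note table is a delimited text file (tab by default) with a header and
#' four columns: `id`, `date` (ISO-8601), `text` and `codes` (ICD-10-CM codes
#' separated by `";"`).
#'
#' @param path file path.
#' @param sep field separator.
#' @return `read_notes` returns a data.frame with columns `id` (character),
#'   `date` (`Date`), `text` and `codes` (character).
#' @export
read_notes <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", comment.char = "",
                          stringsAsFactors = FALSE)
  need <- c("id", "date", "text", "codes")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("note table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[need]
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("note table has unparseable dates (expect ISO-8601)")
  df
}

#' @rdname read_notes
#' @param notes data.frame with columns `id`, `date`, `text`, `codes`.
#' @export
write_notes <- function(notes, path, sep = "\t") {
  df <- data.frame(id = as.character(notes$id),
                   date = format(as.Date(notes$date)),
                   text = as.character(notes$text),
                   codes = as.character(notes$codes),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' A toy synonym dictionary
#'
#' Synonym integration is pluggable: a dictionary is a named character vector
#' mapping terms to category identifiers. [apply_synonyms()] appends one
#' `cat:<category>` pseudo-token per matching term occurrence, so categories
#' become ordinary bag-of-words features. The bundled toy dictionary covers a
#' handful of oncology and infection terms; substitute a full vocabulary
#' mapping by passing your own named vector.
#'
#' @return named character vector (term -> category).
#' @export
toy_synonym_dictionary <- function() {
  c(carcinoma = "neoplasm", adenocarcinoma = "neoplasm", tumor = "neoplasm",
    tumour = "neoplasm", lymphoma = "neoplasm", metastasis = "neoplasm",
    influenza = "infection", flu = "infection", pneumonia = "infection",
    sepsis = "infection", abscess = "infection")
}

#' @rdname toy_synonym_dictionary
#' @param tokens list of token vectors, as produced by [tokenize()].
#' @param dictionary named character vector (term -> category); `NULL`
#'   disables synonym expansion.
#' @export
apply_synonyms <- function(tokens, dictionary = toy_synonym_dictionary()) {
  if (is.null(dictionary) || length(dictionary) == 0L) return(tokens)
  lapply(tokens, function(tk) {
    hit <- dictionary[match(tk, names(dictionary))]
    c(tk, paste0("cat:", hit[!is.na(hit)]))
  })
}
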