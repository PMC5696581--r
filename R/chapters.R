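#' The 21 chapter-level ICD-10-CM code ranges
#'
#' Returns the chapter table of the 2017 ICD-10-CM: 21 top-level code ranges
#' (e.g. `C00-D49`, Neoplasms), each with its start and end three-character
#' bounds and a short definition. These ranges are the label space when
#' diagnosis codes are truncated to chapter level.
#'
#' @return A data.frame with columns `chapter`, `start`, `end`, `definition`,
#'   one row per chapter, in code order.
#' @export
#' @examples
#' icd10_chapters()$chapter
icd10_chapters <- function() {
  .icd10_chapter_table
}

.icd10_chapter_table <- data.frame(
  chapter = c("A00-B99", "C00-D49", "D50-D89", "E00-E89", "F01-F99",
              "G00-G99", "H00-H59", "H60-H95", "I00-I99", "J00-J99",
              "K00-K95", "L00-L99", "M00-M99", "N00-N99", "O00-O9A",
              "P00-P96", "Q00-Q99", "R00-R99", "S00-T88", "V00-Y99",
              "Z00-Z99"),
  start = c("A00", "C00", "D50", "E00", "F01", "G00", "H00", "H60", "I00",
            "J00", "K00", "L00", "M00", "N00", "O00", "P00", "Q00", "R00",
            "S00", "V00", "Z00"),
  end = c("B99", "D49", "D89", "E89", "F99", "G99", "H59", "H95", "I99",
          "J99", "K95", "L99", "M99", "N99", "O9A", "P96", "Q99", "R99",
          "T88", "Y99", "Z99"),
  definition = c(
    "Certain infectious and parasitic diseases",
    "Neoplasms",
    "Diseases of the blood and blood-forming organs and certain disorders involving the immune mechanism",
    "Endocrine, nutritional, and metabolic diseases",
    "Mental, behavioral, and neurodevelopmental disorders",
    "Diseases of the nervous system",
    "Diseases of the eye and adnexa",
    "Diseases of the ear and mastoid process",
    "Diseases of the circulatory system",
    "Diseases of the respiratory system",
    "Diseases of the digestive system",
    "Diseases of the skin and subcutaneous tissue",
    "Diseases of the musculoskeletal system and connective tissue",
    "Diseases of the genitourinary system",
    "Pregnancy, childbirth, and the puerperium",
    "Certain conditions originating in the perinatal period",
    "Congenital malformations, deformations, and chromosomal abnormalities",
    "Symptoms, signs, and abnormal clinical and laboratory findings, not elsewhere classified",
    "Injury, poisoning, and certain other consequences of external causes",
    "External causes of morbidity",
    "Factors influencing health status and contact with health services"),
  stringsAsFactors = FALSE
)

# Encode a 3-character prefix as a sortable number: letter * 1000 + 10 * tens
# + units. "O9A" (a legal ICD-10-CM prefix: obstetric codes run O00-O9A) sorts
# just above O99.
.encode_prefix <- function(prefix) {
  out <- rep(NA_real_, length(prefix))
  special <- prefix == "O9A"
  out[special] <- (match("O", LETTERS)) * 1000 + 995
  ok <- !special & grepl("^[A-Z][0-9][0-9]$", prefix)
  out[ok] <- match(substr(prefix[ok], 1, 1), LETTERS) * 1000 +
    as.numeric(substr(prefix[ok], 2, 3)) * 10
  out
}

#' Map ICD-10-CM codes to chapter-level categories
#'
#' Truncates each code to its first three characters and assigns the chapter
#' whose code range contains it. Assignment uses half-open intervals on the
#' ordered chapter start bounds, so a prefix maps to the chapter with the
#' greatest start bound not exceeding it; prefixes falling in the short gaps
#' between chapter ranges (which contain no billable 2017 codes) inherit the
#' preceding chapter, making the mapping total on A00-Z99.
#'
#' @param codes character vector of ICD-10-CM codes (e.g. `"C50.911"`). A code
#'   must start with a letter followed by at least two alphanumerics.
#' @param table chapter table as returned by [icd10_chapters()].
#' @return character vector of chapter identifiers (e.g. `"C00-D49"`).
#' @export
#' @examples
#' map_code_to_chapter(c("C50.911", "D50.0", "O9A1"))
map_code_to_chapter <- function(codes, table = icd10_chapters()) {
  if (length(codes) == 0L) return(character(0))
  codes <- as.character(codes)
  prefix <- toupper(substr(codes, 1, 3))
  bad <- is.na(codes) | nchar(codes) < 3L |
    !(grepl("^[A-Z][0-9][0-9A-Za-z]", toupper(codes)))
  key <- .encode_prefix(prefix)
  bad <- bad | is.na(key)
  starts <- .encode_prefix(table$start)
  idx <- findInterval(key, starts)
  bad <- bad | (!is.na(key) & idx < 1L)
  if (any(bad)) {
    stop("cannot map ICD-10-CM code(s) to a chapter: ",
         paste(unique(codes[bad]), collapse = ", "))
  }
  table$chapter[idx]
}

#' Derive the chapter label set of each note
#'
#' @param codes_field character vector, one element per note, holding the
#'   note's ICD-10-CM codes separated by `sep` (empty string for none).
#' @param sep separator between codes within a field.
#' @param table chapter table, see [icd10_chapters()].
#' @return list of character vectors: the distinct chapters of each note.
#' @export
note_chapters <- function(codes_field, sep = ";", table = icd10_chapters()) {
  lapply(strsplit(as.character(codes_field), sep, fixed = TRUE), function(cc) {
    cc <- trimws(cc)
    cc <- cc[nzchar(cc)]
    if (length(cc) == 0L) return(character(0))
    sort(unique(map_code_to_chapter(cc, table)))
  })
}
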