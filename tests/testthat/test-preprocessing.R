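test_that("tokenizer lowercases, strips punctuation and keeps digit tokens", {
  expect_equal(tokenize("Acute MI, s/p PCI.")[[1]],
               c("acute", "mi", "s", "p", "pci"))
  expect_equal(tokenize("")[[1]], character(0))
  expect_equal(tokenize("H1N1 influenza")[[1]], c("h1n1", "influenza"))
  expect_equal(tokenize(c("a b", "c"))[[2]], "c")
  expect_equal(tokenize(NA_character_)[[1]], character(0))
})

test_that("chapter table has 21 disjoint ordered ranges", {
  tab <- icd10_chapters()
  expect_equal(nrow(tab), 21L)
  expect_equal(anyDuplicated(tab$chapter), 0L)
  starts <- icdcnn:::.encode_prefix(tab$start)
  ends <- icdcnn:::.encode_prefix(tab$end)
  expect_true(all(diff(starts) > 0))
  expect_true(all(ends >= starts))
  # each range ends before the next begins
  expect_true(all(ends[-21] < starts[-1]))
})

test_that("codes map to the chapter containing their 3-character prefix", {
  expect_equal(map_code_to_chapter("C50.911"), "C00-D49")
  expect_equal(map_code_to_chapter("D50.0"), "D50-D89")
  expect_equal(map_code_to_chapter("O9A1"), "O00-O9A")
  expect_equal(map_code_to_chapter("J18.9"), "J00-J99")
  tab <- icd10_chapters()
  # every range endpoint maps to its own chapter; 21 distinct results
  expect_equal(map_code_to_chapter(paste0(tab$start, "0")), tab$chapter)
  expect_equal(map_code_to_chapter(paste0(tab$end, "0")), tab$chapter)
  expect_length(unique(map_code_to_chapter(paste0(tab$start, "0"))), 21L)
  expect_error(map_code_to_chapter("ZZ9"), "ZZ9")
  expect_error(map_code_to_chapter("A0"), "A0")
  expect_error(map_code_to_chapter("9AB"), "9AB")
  expect_equal(map_code_to_chapter("c50"), "C00-D49")
})

test_that("note_chapters derives sorted unique chapter sets", {
  ch <- note_chapters(c("C50.911;C34.1;I10", "", "D50.0"))
  expect_equal(ch[[1]], c("C00-D49", "I00-I99"))
  expect_equal(ch[[2]], character(0))
  expect_equal(ch[[3]], "D50-D89")
})

test_that("n-gram extraction enumerates windows and filters by strict count", {
  expect_setequal(extract_ngrams(list(c("a", "b", "c")), 2, 5, 0),
                  c("a b", "b c", "a b c"))
  expect_equal(extract_ngrams(list("a"), 2, 5, 0), character(0))
  expect_equal(extract_ngrams(list(), 2, 5, 0), character(0))
  # a phrase occurring exactly 10 times is excluded at threshold 10,
  # included at 11 occurrences
  corp10 <- rep(list(c("x", "y")), 10)
  expect_false("x y" %in% extract_ngrams(corp10, 2, 2, 10))
  corp11 <- rep(list(c("x", "y")), 11)
  expect_true("x y" %in% extract_ngrams(corp11, 2, 2, 10))
})

test_that("n-gram sets are monotone in the count threshold", {
  set.seed(7)
  vocab <- letters[1:6]
  corp <- lapply(1:30, function(i) sample(vocab, sample(3:10, 1), replace = TRUE))
  for (k in 0:4) {
    hi <- extract_ngrams(corp, 2, 4, k + 1)
    lo <- extract_ngrams(corp, 2, 4, k)
    expect_true(all(hi %in% lo))
  }
})

test_that("document-term matrix counts features per note", {
  dtm <- build_document_term_matrix(list(c("a", "b", "a")), c("a", "b", "z"))
  expect_equal(as.numeric(dtm[1, ]), c(2, 1, 0))
  expect_equal(colnames(dtm), c("a", "b", "z"))
  expect_error(build_document_term_matrix(list("a"), character(0)), "empty")
})

test_that("document-term matrix equals a naive per-note recount", {
  set.seed(11)
  vocab <- letters[1:5]
  corp <- lapply(1:100, function(i) sample(vocab, sample(2:12, 1), replace = TRUE))
  feats <- corpus_features(corp, min_count_exclusive = 3)
  dtm <- build_document_term_matrix(corp, feats)
  naive_count <- function(tokens, feat) {
    n <- length(strsplit(feat, " ", fixed = TRUE)[[1]])
    if (length(tokens) < n) return(0)
    grams <- vapply(seq_len(length(tokens) - n + 1), function(t) {
      paste(tokens[t:(t + n - 1)], collapse = " ")
    }, character(1))
    sum(grams == feat)
  }
  for (i in sample(100, 20)) {
    expected <- vapply(feats, naive_count, numeric(1), tokens = corp[[i]])
    expect_equal(as.numeric(dtm[i, ]), unname(expected))
  }
  # row sums cannot exceed the window count of the note
  expect_true(all(Matrix::rowSums(dtm) <=
                    vapply(corp, function(tk) length(tk) * 4, numeric(1))))
})

test_that("unigram features are unfiltered; phrase features obey the filter", {
  corp <- c(rep(list(c("rare", "pair")), 2), list(c("common")))
  feats <- corpus_features(corp, min_count_exclusive = 10)
  expect_true(all(c("rare", "pair", "common") %in% feats))
  expect_false("rare pair" %in% feats)
})

test_that("synonym dictionary appends one category token per matching term", {
  tk <- apply_synonyms(list(c("invasive", "carcinoma", "carcinoma")),
                       toy_synonym_dictionary())
  expect_equal(sum(tk[[1]] == "cat:neoplasm"), 2L)
  feats <- corpus_features(list(c("carcinoma", "x")),
                           dictionary = toy_synonym_dictionary())
  expect_true("cat:neoplasm" %in% feats)
  dtm <- build_document_term_matrix(tk, feats)
  expect_equal(as.numeric(dtm[1, "cat:neoplasm"]), 2)
})

test_that("note tables round-trip through the TSV reader/writer", {
  notes <- data.frame(id = c("n1", "n2"),
                      date = as.Date(c("2016-06-30", "2016-07-01")),
                      text = c("acute mi", "fracture of femur"),
                      codes = c("I21.9;I10", ""),
                      stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_notes(notes, path)
  back <- read_notes(path)
  expect_equal(back$id, notes$id)
  expect_equal(back$date, notes$date)
  expect_equal(back$text, notes$text)
  expect_equal(back$codes, notes$codes)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("id\tdate\ttext", path2)
  expect_error(read_notes(path2), "codes")
})
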