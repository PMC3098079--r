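xml_doc <- '<article doc-id="a1">
<front><article-title>Mapping loci</article-title>
<abstract>We mapped loci. They were novel.</abstract></front>
<body><sec sec-type="results">Results text here.</sec>
<sec sec-type="other">More text.</sec></body>
<back><ref-list>Ref 1. Ref 2.</ref-list></back>
</article>'

test_that("XML dialect maps abstract, secs and ref-list to section kinds", {
  doc <- read_document(xml_doc)
  expect_s3_class(doc, "sectioned_document")
  expect_equal(doc$doc_id, "a1")
  expect_equal(doc$sections$kind,
               c("title", "abstract", "results", "other", "bibliography"))
  # unknown sec-type labels map to other
  d2 <- read_document('<article><front><abstract>A.</abstract></front>
    <body><sec sec-type="weird">B.</sec><sec>C.</sec></body></article>')
  expect_equal(d2$sections$kind, c("abstract", "other", "other"))
})

test_that("plain-text dialect maps headers and unknown labels", {
  txt <- "== ABSTRACT ==\nWe mapped loci.\n== RESULTS ==\nThey were novel.\n== FROBNICATION ==\nOdd."
  doc <- read_document(txt, format = "text")
  expect_equal(doc$sections$kind, c("abstract", "results", "other"))
  expect_equal(doc$sections$text[1], "We mapped loci.")
})

test_that("malformed and empty inputs error", {
  expect_error(read_document("<article><front>"), "malformed")
  expect_error(read_document("   \n  "), "empty")
})

test_that("plain-text round-trip preserves kinds and texts", {
  doc <- read_document(xml_doc)
  back <- read_document(write_document_text(doc), format = "text")
  expect_equal(back$sections$kind, doc$sections$kind)
  expect_equal(back$sections$text, doc$sections$text)
  # and for generated documents too
  cp <- generate_corpus(small_spec(n_docs = 2, seed = 3))
  for (d in cp$documents) {
    b <- read_document(write_document_text(d), format = "text")
    expect_equal(b$sections$text, d$sections$text)
  }
})

test_that("JSON dump carries doc_id and sections", {
  doc <- read_document(xml_doc)
  parsed <- jsonlite::fromJSON(write_document_json(doc))
  expect_equal(parsed$doc_id, "a1")
  expect_equal(parsed$sections$kind, doc$sections$kind)
})

test_that("genre partition obeys title and bibliography flags", {
  doc <- sectioned_document("d", c("title", "abstract", "results",
                                   "bibliography"),
                            c("T", "A", "R", "B"))
  p <- partition_genres(doc)  # defaults: title in, bibliography out
  expect_equal(p$abstract_text, "T\nA")
  expect_equal(p$body_text, "R")
  p2 <- partition_genres(doc, include_title = FALSE,
                         include_bibliography = TRUE)
  expect_equal(p2$abstract_text, "A")
  expect_equal(p2$body_text, "R\nB")
  # abstract-only document: empty body
  p3 <- partition_genres(sectioned_document("d", "abstract", "Only."))
  expect_equal(p3$body_text, "")
  expect_error(density_per_thousand(1, count_tokens(p3$body_text)))
})

test_that("a document allows at most one abstract and one title", {
  expect_error(sectioned_document("d", c("abstract", "abstract"),
                                  c("A", "B")), "at most one")
})

test_that("sentence segmentation: boundaries, parens, abbreviations", {
  expect_equal(nrow(segment_sentences("We mapped loci. They were novel.")),
               2L)
  expect_equal(nrow(segment_sentences("The value (P < .01) was low.")), 1L)
  expect_equal(
    nrow(segment_sentences("Results from Smith et al. 1999 were confirmed.")),
    1L)
  s <- segment_sentences("First here. Second there.")
  expect_equal(s$text, c("First here.", "Second there."))
  # spans index into the original text (0-based half-open)
  txt <- "  One two.  Three four.  "
  sp <- segment_sentences(txt)
  expect_equal(substring(txt, sp$start + 1, sp$end),
               c("One two.", "Three four."))
})

test_that("sentence spans never split a balanced parenthesis pair", {
  set.seed(99)
  words <- c("alpha", "beta", "Gamma", "delta")
  for (rep in 1:20) {
    n <- sample(8:20, 1)
    toks <- sample(words, n, replace = TRUE)
    # insert a parenthesized chunk containing a period
    at <- sample(2:(n - 1), 1)
    toks[at] <- "(P < .01. Also 3.5)"
    txt <- paste(paste(toks, collapse = " "), ".", sep = "")
    sp <- segment_sentences(txt)
    for (i in seq_len(nrow(sp))) {
      piece <- sp$text[i]
      expect_equal(lengths(regmatches(piece, gregexpr("(", piece,
                                                      fixed = TRUE))),
                   lengths(regmatches(piece, gregexpr(")", piece,
                                                      fixed = TRUE))))
    }
  }
})

test_that("whitespace tokenization counts maximal runs and is additive", {
  expect_length(tokenize_whitespace("We mapped two quantitative trait loci (QTLs)"),
                7L)
  expect_length(tokenize_whitespace(""), 0L)
  expect_length(tokenize_whitespace("a  b"), 2L)
  set.seed(4)
  for (rep in 1:10) {
    a <- paste(sample(letters, sample(3:9, 1), replace = TRUE),
               collapse = " ")
    b <- paste(sample(letters, sample(3:9, 1), replace = TRUE),
               collapse = " ")
    expect_equal(count_tokens(paste(a, b)),
                 count_tokens(a) + count_tokens(b))
  }
})
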