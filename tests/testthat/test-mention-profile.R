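test_that("dictionary filtering applies the four rules with tallies", {
  raw <- c("aspirin", "gold", "1,2-bis(2-aminophenoxy)ethane", "lysine",
           "water", "warfarin", "folic acid", "abc[1]def")
  kept <- filter_dictionary(raw)
  expect_setequal(as.vector(kept), c("aspirin", "warfarin", "folic acid"))
  removed <- attr(kept, "removed")
  expect_equal(removed[["special_chars"]], 2L)   # parens + brackets
  expect_equal(removed[["amino_acid"]], 1L)      # lysine
  expect_equal(removed[["english_word"]], 1L)    # water
  expect_equal(removed[["too_short"]], 1L)       # gold (4 chars)
})

test_that("amino-acid codes and names are filtered case-insensitively", {
  kept <- filter_dictionary(c("Glycine", "TRP", "novel-compound-x"))
  expect_equal(as.vector(kept), "novel-compound-x")
})

test_that("matching requires full words, ignores case and edge punctuation", {
  dict <- filter_dictionary(c("aspirin", "folic acid"))
  m1 <- dictionary_match("treated with aspirin.", dict)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$text, "aspirin")
  expect_equal(nrow(dictionary_match("aspirinlike effect", dict)), 0L)
  m2 <- dictionary_match("given folic acid daily", dict)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$text, "folic acid")
  m3 <- dictionary_match("Aspirin, was given", dict)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$text, "Aspirin")
  # offsets are 0-based half-open and exclude punctuation
  t <- "treated with aspirin."
  expect_equal(substr(t, m1$start + 1, m1$end), "aspirin")
})

test_that("overlapping candidates resolve longest-first, left-to-right", {
  dict <- filter_dictionary(c("folic acid", "acidx"))
  dict2 <- c("folic", "folic acid")  # pre-filtered on purpose
  m <- dictionary_match("given folic acid daily", dict2)
  expect_equal(m$text, "folic acid")  # longest wins over its prefix
})

test_that("match output is invariant to dictionary entry order", {
  text <- "aspirin then warfarin then folic acid"
  d1 <- c("aspirin", "warfarin", "folic acid")
  d2 <- rev(d1)
  m1 <- dictionary_match(text, d1)
  m2 <- dictionary_match(text, d2)
  expect_equal(m1[order(m1$start), ], m2[order(m2$start), ])
})

test_that("density report reproduces counts, densities and coverage", {
  men <- mention_set(
    doc_id = c("d1", "d1", "d2", "d1"),
    genre = c("abstract", "body", "body", "body"),
    start = c(0, 10, 20, 40), end = c(5, 15, 25, 45),
    text = "x", class = c("drug", "drug", "drug", "gene"))
  rep <- density_report(men, word_totals = c(abstract = 1000, body = 2000),
                        doc_counts = c(abstract = 2L, body = 2L))
  drug_body <- rep[rep$class == "drug" & rep$genre == "body", ]
  expect_equal(drug_body$count, 2L)
  expect_equal(drug_body$per_thousand, 1.0)
  expect_equal(drug_body$docs_mentioning, 2L)
  expect_equal(drug_body$mean_per_doc, 1.0)
  expect_error(density_report(men, c(abstract = 0, body = 10),
                              c(abstract = 1L, body = 1L)), "zero")
})

test_that("docs-mentioning equals a brute-force distinct-doc oracle", {
  set.seed(61)
  for (rep_i in 1:5) {
    n <- sample(5:30, 1)
    men <- mention_set(
      doc_id = sample(paste0("d", 1:6), n, replace = TRUE),
      genre = sample(c("abstract", "body"), n, replace = TRUE),
      start = seq(0, by = 10, length.out = n),
      end = seq(5, by = 10, length.out = n),
      text = "x", class = sample(c("gene", "drug"), n, replace = TRUE))
    rep_ <- density_report(men, c(abstract = 500, body = 500),
                           c(abstract = 6L, body = 6L))
    for (i in seq_len(nrow(rep_))) {
      seen <- unique(men$doc_id[men$class == rep_$class[i] &
                                  men$genre == rep_$genre[i]])
      expect_equal(rep_$docs_mentioning[i], length(seen))
    }
  }
})

test_that("mention TSV round-trips", {
  men <- mention_set(c("d1", "d2"), c("abstract", "body"), c(0L, 7L),
                     c(4L, 12L), c("Gata", "aspir"), c("gene", "drug"))
  path <- tempfile(fileext = ".tsv")
  write_mentions_tsv(men, path)
  back <- read_mentions_tsv(path)
  expect_equal(back, men)
})

test_that("planted mention densities are recovered within Poisson bounds", {
  sp <- small_spec(n_docs = 10, seed = 51, body_sentences = 120)
  cp <- generate_corpus(sp)
  W <- cp$token_totals[["body"]]
  gold_body <- cp$mentions[cp$mentions$genre == "body", ]
  for (cl in c("gene", "drug", "disease")) {
    d <- sp$body$mention_rates[[cl]]
    est <- sum(gold_body$class == cl) * 1000 / W
    expect_lt(abs(est - d), 3 * sqrt(d * 1000 / W), label = cl)
  }
  # the dictionary matcher recovers planted drug mentions exactly
  dict <- filter_dictionary(synthetic_drug_dictionary())
  hits <- do.call(rbind, lapply(names(cp$genre_texts$body), function(id)
    dictionary_match(cp$genre_texts$body[[id]], dict, doc_id = id,
                     genre = "body")))
  gold_drug <- gold_body[gold_body$class == "drug", ]
  cc <- match_spans(gold_drug, hits)
  expect_equal(cc$FN, 0L)
  expect_equal(cc$FP, 0L)
})
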