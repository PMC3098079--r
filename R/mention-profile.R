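ENTITY_CLASSES <- c("gene", "mutation", "drug", "disease")

#' Construct a mention set
#'
#' A mention set holds entity mentions as character-offset spans (0-based,
#' half-open) within a genre's text: gold annotations, tagger predictions,
#' or dictionary matches.
#'
#' @param doc_id,genre,start,end,text,class Parallel vectors (recycled where
#'   scalar): document id, genre label (`abstract`/`body`), span offsets,
#'   matched text, entity class (one of gene, mutation, drug, disease).
#' @return Data frame of class `mention_set`.
#' @export
mention_set <- function(doc_id = character(0), genre = character(0),
                        start = integer(0), end = integer(0),
                        text = character(0), class = character(0)) {
  n <- max(length(doc_id), length(genre), length(start), length(end),
           length(text), length(class))
  if (n > 0L) {
    doc_id <- rep_len(doc_id, n); genre <- rep_len(genre, n)
    start <- rep_len(as.integer(start), n); end <- rep_len(as.integer(end), n)
    text <- rep_len(text, n); class <- rep_len(class, n)
    if (any(start < 0L) || any(start >= end))
      stop("invalid spans: need 0 <= start < end")
  }
  structure(data.frame(doc_id = doc_id, genre = genre, start = start,
                       end = end, class = class, text = text,
                       stringsAsFactors = FALSE),
            class = c("mention_set", "data.frame"))
}

#' Read/write mention annotations
#'
#' TSV columns: `doc_id`, `genre`, `start`, `end`, `class`, `text`; offsets
#' 0-based half-open within the genre text.
#'
#' @param path File path.
#' @return A `mention_set` (for the reader).
#' @export
read_mentions_tsv <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         quote = "", comment.char = "")
  mention_set(d$doc_id, d$genre, d$start, d$end, d$text, d$class)
}

#' @rdname read_mentions_tsv
#' @param mentions A `mention_set`.
#' @export
write_mentions_tsv <- function(mentions, path) {
  utils::write.table(mentions[, c("doc_id", "genre", "start", "end",
                                  "class", "text")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standard amino-acid name filter list
#'
#' The 20 standard amino acids' full names and three-letter codes; drug
#' dictionaries inherited from compound databases list these as entries, and
#' they match protein-chemistry prose rather than drug mentions.
#'
#' @return Character vector (lower-case).
#' @export
amino_acid_names <- function() {
  full <- c("alanine", "arginine", "asparagine", "aspartate",
            "aspartic acid", "cysteine", "glutamine", "glutamate",
            "glutamic acid", "glycine", "histidine", "isoleucine",
            "leucine", "lysine", "methionine", "phenylalanine", "proline",
            "serine", "threonine", "tryptophan", "tyrosine", "valine")
  codes <- c("ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly", "his",
             "ile", "leu", "lys", "met", "phe", "pro", "ser", "thr", "trp",
             "tyr", "val")
  c(full, codes)
}

#' Default general-English filter wordlist
#'
#' @return Character vector of common English words (lower-case), from the
#'   plain-text file shipped with the package; a configurable input — pass
#'   any frequency list to [filter_dictionary()].
#' @export
default_english_words <- function() {
  path <- system.file("extdata", "english_words.txt", package = "genreprof")
  w <- readLines(path, warn = FALSE)
  w[nzchar(w) & !startsWith(w, "#")]
}

#' Filter a drug-name dictionary
#'
#' Removes, in order: (a) names containing any of the characters
#' `( ) [ ] + .` (regex metacharacters that break naive matching); (b)
#' amino-acid names; (c) general-English words; (d) names shorter than five
#' characters. Each removed name is tallied under the first rule it trips.
#'
#' @param raw_entries Character vector of names, one per entry.
#' @param english_words Lower-case general-English wordlist.
#' @param amino_acids Lower-case amino-acid name list.
#' @param min_chars Minimum name length (default 5).
#' @return Character vector of surviving names, with attribute `removed`
#'   (named integer tallies per rule: `special_chars`, `amino_acid`,
#'   `english_word`, `too_short`).
#' @export
filter_dictionary <- function(raw_entries,
                              english_words = default_english_words(),
                              amino_acids = amino_acid_names(),
                              min_chars = 5L) {
  x <- trimws(raw_entries)
  x <- x[nzchar(x)]
  low <- tolower(x)
  special <- grepl("[][()+.]", x)
  amino <- !special & low %in% tolower(amino_acids)
  english <- !special & !amino & low %in% tolower(english_words)
  short <- !special & !amino & !english & nchar(x) < min_chars
  keep <- !(special | amino | english | short)
  out <- unique(x[keep])
  attr(out, "removed") <- c(special_chars = sum(special),
                            amino_acid = sum(amino),
                            english_word = sum(english),
                            too_short = sum(short))
  out
}

# Token cores of a text with character offsets: maximal non-whitespace runs
# with edge punctuation stripped off both the string and the offsets.
token_cores <- function(text) {
  m <- gregexpr("[^[:space:]]+", text)[[1]]
  if (m[1] == -1L)
    return(data.frame(core = character(0), start = integer(0),
                      end = integer(0)))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  toks <- substring(text, starts, starts + lens - 1L)
  lead <- nchar(sub("^([[:punct:]]*).*$", "\\1", toks))
  trail <- nchar(toks) - nchar(sub("[[:punct:]]+$", "", toks))
  trail[lead + trail >= nchar(toks)] <- 0L  # all-punct token: keep as-is
  core_start <- starts + lead
  core_end <- starts + lens - 1L - trail
  keep <- core_end >= core_start
  data.frame(core = substring(text, core_start, core_end)[keep],
             start = core_start[keep], end = core_end[keep],
             stringsAsFactors = FALSE)
}

#' Dictionary-based mention matching
#'
#' Case-insensitive longest match over whole words: a match's boundaries
#' must coincide with token boundaries after edge punctuation is stripped,
#' multi-word entries match across single spaces, and overlapping candidates
#' are resolved longest-first, left-to-right. The result does not depend on
#' dictionary entry order.
#'
#' @param genre_text Character scalar.
#' @param dictionary Filtered dictionary (character vector; see
#'   [filter_dictionary()]).
#' @param doc_id,genre Labels stamped on every match.
#' @param class Entity class of the dictionary (default `"drug"`).
#' @return A `mention_set` with offsets into `genre_text` (0-based,
#'   half-open, punctuation excluded).
#' @export
dictionary_match <- function(genre_text, dictionary, doc_id = "doc",
                             genre = "body", class = "drug") {
  tk <- token_cores(genre_text)
  n <- nrow(tk)
  out_start <- integer(0); out_end <- integer(0); out_text <- character(0)
  if (n == 0L || length(dictionary) == 0L)
    return(mention_set(character(0)))
  entries <- tolower(trimws(dictionary))
  entry_words <- strsplit(entries, "[[:space:]]+")
  maxw <- max(lengths(entry_words))
  lookup <- new.env(parent = emptyenv(), hash = TRUE)
  for (e in unique(entries)) assign(e, TRUE, envir = lookup)
  low <- tolower(tk$core)
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (k in seq(min(maxw, n - i + 1L), 1L)) {
      key <- paste(low[i:(i + k - 1L)], collapse = " ")
      if (!is.null(lookup[[key]])) { matched <- k; break }
    }
    if (matched > 0L) {
      a <- tk$start[i]; b <- tk$end[i + matched - 1L]
      out_start <- c(out_start, a - 1L)   # to 0-based
      out_end <- c(out_end, b)            # half-open
      out_text <- c(out_text, substr(genre_text, a, b))
      i <- i + matched
    } else i <- i + 1L
  }
  mention_set(doc_id = rep(doc_id, length(out_start)),
              genre = rep(genre, length(out_start)),
              start = out_start, end = out_end, text = out_text,
              class = rep(class, length(out_start)))
}

#' Mention density report
#'
#' Per entity class and genre: mention count, word total, density per
#' thousand words, number of documents with at least one mention, and mean
#' mentions per document.
#'
#' @param mentions A `mention_set` (possibly several classes).
#' @param word_totals Named numeric vector: words per genre (names are
#'   genre labels); all entries must be positive.
#' @param doc_counts Named integer vector: number of documents per genre.
#' @return Data frame of class `density_report` with one row per
#'   (class, genre).
#' @export
density_report <- function(mentions, word_totals, doc_counts) {
  if (any(word_totals <= 0)) stop("zero word total: density undefined")
  genres <- names(word_totals)
  stopifnot(!is.null(genres), setequal(genres, names(doc_counts)))
  classes <- unique(c(mentions$class, character(0)))
  if (length(classes) == 0L) classes <- "none"
  rows <- expand.grid(class = classes, genre = genres,
                      stringsAsFactors = FALSE)
  rows$count <- mapply(function(cl, g)
    sum(mentions$class == cl & mentions$genre == g),
    rows$class, rows$genre)
  rows$word_total <- word_totals[rows$genre]
  rows$per_thousand <- density_per_thousand(rows$count, rows$word_total)
  rows$docs_mentioning <- mapply(function(cl, g)
    length(unique(mentions$doc_id[mentions$class == cl &
                                    mentions$genre == g])),
    rows$class, rows$genre)
  rows$docs_total <- doc_counts[rows$genre]
  rows$mean_per_doc <- rows$count / rows$docs_total
  rownames(rows) <- NULL
  structure(rows, class = c("density_report", "data.frame"))
}
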