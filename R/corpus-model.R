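#' @keywords internal
"_PACKAGE"

SECTION_KINDS <- c("title", "abstract", "introduction", "methods", "results",
                   "discussion", "conclusions", "captions", "bibliography",
                   "other")

#' Construct a sectioned document
#'
#' A `sectioned_document` is an article split into an ordered sequence of
#' titled sections, each carrying a kind (abstract, results, bibliography,
#' ...), its text, and its 0-based character offset within the concatenated
#' document text. It is the input to the genre partition that defines the two
#' text populations compared throughout the package: the abstract genre and
#' the body genre.
#'
#' @param doc_id Character scalar identifier.
#' @param kinds Character vector of section kinds; each must be one of
#'   `r paste(SECTION_KINDS, collapse = ", ")`.
#' @param texts Character vector of section texts, same length as `kinds`.
#' @return An object of class `sectioned_document`: a list with `doc_id` and
#'   a `sections` data frame (`kind`, `text`, `char_offset`).
#' @export
sectioned_document <- function(doc_id, kinds, texts) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            length(kinds) == length(texts))
  kinds <- as.character(kinds)
  texts <- as.character(texts)
  bad <- setdiff(kinds, SECTION_KINDS)
  if (length(bad) > 0L)
    stop("unknown section kind(s): ", paste(bad, collapse = ", "))
  if (sum(kinds == "abstract") > 1L)
    stop("at most one 'abstract' section is allowed")
  if (sum(kinds == "title") > 1L)
    stop("at most one 'title' section is allowed")
  offs <- c(0L, cumsum(nchar(texts, type = "bytes")))[seq_along(texts)]
  structure(
    list(doc_id = doc_id,
         sections = data.frame(kind = kinds, text = texts,
                               char_offset = as.integer(offs),
                               stringsAsFactors = FALSE)),
    class = "sectioned_document")
}

#' @export
print.sectioned_document <- function(x, ...) {
  cat("<sectioned_document> ", x$doc_id, "\n", sep = "")
  with(x$sections,
       cat(sprintf("  %-13s %7d chars @%d\n", kind, nchar(text), char_offset),
           sep = ""))
  invisible(x)
}

# Map a free-form section label (XML sec-type or plain-text header) to a kind.
normalize_section_kind <- function(label) {
  lab <- tolower(trimws(label))
  lab <- sub("s$", "", lab)  # "methods"/"method", "results"/"result"
  kind <- switch(lab,
    "title" = "title",
    "abstract" = "abstract",
    "intro" = , "introduction" = , "background" = "introduction",
    "method" = , "material" = , "materials and method" = ,
    "materials and methods" = "methods",
    "result" = , "results and discussion" = "results",
    "discussion" = "discussion",
    "conclusion" = "conclusions",
    "caption" = , "figure caption" = , "fig" = "captions",
    "bibliography" = , "reference" = , "ref-list" = "bibliography",
    NULL)
  if (is.null(kind)) "other" else kind
}

#' Read a sectioned article
#'
#' Reads one article in either of the two supported dialects and returns a
#' [sectioned_document]. Dialect 1 is a minimal PMC-style XML format:
#' `<article>` with `<front>/<article-title>`, `<front>/<abstract>`,
#' `<body>/<sec sec-type="...">` and an optional `<back>/<ref-list>`.
#' Dialect 2 is plain text in which lines of the form `== NAME ==` introduce
#' sections. Unknown section labels map to kind `other`.
#'
#' @param source Path to the input file, or a character scalar holding its
#'   contents.
#' @param format `"auto"` (default; sniffs for a leading `<`), `"xml"`, or
#'   `"text"`.
#' @param doc_id Identifier to use when the input does not carry one;
#'   defaults to the file base name or `"doc"`.
#' @return A [sectioned_document].
#' @export
read_document <- function(source, format = c("auto", "xml", "text"),
                          doc_id = NULL) {
  format <- match.arg(format)
  if (length(source) == 1L && !grepl("[\n<]", source) && file.exists(source)) {
    if (is.null(doc_id))
      doc_id <- tools::file_path_sans_ext(basename(source))
    source <- paste(readLines(source, warn = FALSE), collapse = "\n")
  }
  raw <- paste(source, collapse = "\n")
  if (!nzchar(trimws(raw))) stop("empty document")
  if (format == "auto")
    format <- if (grepl("^\\s*<", raw)) "xml" else "text"
  if (is.null(doc_id)) doc_id <- "doc"
  if (format == "xml") read_document_xml(raw, doc_id)
  else read_document_text(raw, doc_id)
}

read_document_xml <- function(raw, doc_id) {
  doc <- tryCatch(xml2::read_xml(raw),
                  error = function(e) stop("malformed XML markup: ",
                                           conditionMessage(e), call. = FALSE))
  art <- xml2::xml_find_first(doc, "/article")
  if (inherits(art, "xml_missing")) stop("no <article> root element")
  id_attr <- xml2::xml_attr(art, "doc-id")
  if (!is.na(id_attr) && nzchar(id_attr)) doc_id <- id_attr
  kinds <- character(0); texts <- character(0)
  add <- function(kind, text) {
    kinds <<- c(kinds, kind); texts <<- c(texts, text)
  }
  title <- xml2::xml_find_first(art, "./front/article-title")
  if (!inherits(title, "xml_missing")) add("title", xml2::xml_text(title))
  abst <- xml2::xml_find_first(art, "./front/abstract")
  if (!inherits(abst, "xml_missing")) add("abstract", xml2::xml_text(abst))
  for (sec in xml2::xml_find_all(art, "./body/sec")) {
    lab <- xml2::xml_attr(sec, "sec-type")
    kind <- if (is.na(lab)) "other" else normalize_section_kind(lab)
    add(kind, xml2::xml_text(sec))
  }
  for (rl in xml2::xml_find_all(art, ".//ref-list"))
    add("bibliography", xml2::xml_text(rl))
  if (length(kinds) == 0L) stop("document has no sections")
  sectioned_document(doc_id, kinds, texts)
}

read_document_text <- function(raw, doc_id) {
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  hdr <- grepl("^== .+ ==$", lines)
  if (!any(hdr)) {  # headerless fallback: one 'other' section
    return(sectioned_document(doc_id, "other", raw))
  }
  idx <- which(hdr)
  kinds <- character(0); texts <- character(0)
  for (i in seq_along(idx)) {
    from <- idx[i] + 1L
    to <- if (i < length(idx)) idx[i + 1L] - 1L else length(lines)
    body <- if (from > to) "" else paste(lines[from:to], collapse = "\n")
    # trailing blank line before the next header is a separator, not content
    body <- sub("\n$", "", body)
    label <- sub("^== (.+) ==$", "\\1", lines[idx[i]])
    kinds <- c(kinds, normalize_section_kind(label))
    texts <- c(texts, body)
  }
  sectioned_document(doc_id, kinds, texts)
}

#' Write a sectioned document in the plain-text dialect
#'
#' Inverse of [read_document()] for the `== NAME ==` dialect: re-reading the
#' written file yields sections with identical kinds and texts.
#'
#' @param doc A [sectioned_document].
#' @param path Output path; if `NULL`, the serialized text is returned.
#' @export
write_document_text <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "sectioned_document"))
  chunks <- sprintf("== %s ==\n%s", toupper(doc$sections$kind),
                    doc$sections$text)
  out <- paste(chunks, collapse = "\n")
  if (is.null(path)) return(out)
  writeLines(out, path, sep = "")
  invisible(path)
}

#' Dump a sectioned document as JSON
#'
#' @param doc A [sectioned_document].
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @export
write_document_json <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "sectioned_document"))
  obj <- list(doc_id = doc$doc_id, sections = doc$sections)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Partition a document into abstract and body genres
#'
#' The abstract genre is the title (optionally) plus the abstract; the body
#' genre is everything else, optionally excluding bibliography sections. The
#' two texts are disjoint by construction.
#'
#' @param doc A [sectioned_document].
#' @param include_title Prepend the title to the abstract genre? Default
#'   `TRUE`; sentence-length analyses typically set this `FALSE` because
#'   titles are not sentences.
#' @param include_bibliography Keep bibliography sections in the body genre?
#'   Default `FALSE`.
#' @param sep Separator used when concatenating sections.
#' @return A list of class `genre_partition` with elements `abstract_text`
#'   and `body_text`.
#' @export
partition_genres <- function(doc, include_title = TRUE,
                             include_bibliography = FALSE, sep = "\n") {
  stopifnot(inherits(doc, "sectioned_document"))
  s <- doc$sections
  abst_kinds <- if (include_title) c("title", "abstract") else "abstract"
  in_abst <- s$kind %in% abst_kinds
  in_body <- !(s$kind %in% c("title", "abstract")) &
    (include_bibliography | s$kind != "bibliography")
  structure(list(
    abstract_text = paste(s$text[in_abst], collapse = sep),
    body_text = paste(s$text[in_body], collapse = sep)),
    class = "genre_partition")
}

# Abbreviations whose trailing period never ends a sentence.
biomed_abbreviations <- function() {
  c("al", "e.g", "i.e", "etc", "vs", "cf", "ca", "fig", "figs", "tab",
    "eq", "eqs", "no", "nos", "dr", "st", "approx", "ref", "refs", "resp",
    "spp", "sp", "subsp", "mr", "mrs", "ms", "min", "max", "wt", "mol",
    "vol", "chr")
}

#' Segment text into sentences
#'
#' A rule cascade: a sentence boundary is placed after terminal punctuation
#' (`.`, `!`, `?`, optionally followed by closing quotes/brackets) when the
#' next non-space character starts with a capital letter or digit, the
#' preceding word is not a known abbreviation or a single initial, and the
#' position is not inside a balanced parenthesis pair. The segmenter is
#' pluggable: pass any function mapping text to a data frame of spans via
#' `segmenter` to substitute another splitter.
#'
#' @param text Character scalar.
#' @param abbreviations Character vector of lower-case abbreviations (without
#'   the trailing period) that block a boundary.
#' @param segmenter Optional replacement function `function(text)` returning
#'   the same span data frame; when supplied it is used as-is.
#' @return A data frame with columns `start`, `end` (0-based, half-open
#'   character offsets) and `text`, one row per sentence, in order.
#' @export
segment_sentences <- function(text, abbreviations = biomed_abbreviations(),
                              segmenter = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!is.null(segmenter)) return(segmenter(text))
  n <- nchar(text)
  empty <- data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE)
  if (n == 0L || !nzchar(trimws(text))) return(empty)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  is_space <- grepl("[[:space:]]", chars)
  # candidate boundaries: terminal punctuation at paren depth <= 0 that is
  # followed (possibly through closing quotes/brackets) by whitespace or EOT
  cand <- which(chars %in% c(".", "!", "?") & depth <= 0L)
  boundaries <- integer(0)
  for (i in cand) {
    ch <- chars[i]
    j <- i
    while (j < n && chars[j + 1L] %in% c('"', "'", ")", "]")) j <- j + 1L
    if (j < n && !is_space[j + 1L]) next  # "0.39", "e.g" mid-word
    k <- j + 1L
    while (k <= n && is_space[k]) k <- k + 1L
    if (k == j + 1L && k <= n) next       # no separating space
    if (k <= n && !grepl("[[:upper:][:digit:]]", chars[k])) next
    if (ch == ".") {
      before <- substr(text, 1L, i - 1L)
      m <- regmatches(before, regexpr("[[:alnum:].-]+$", before))
      if (length(m) == 1L) {
        if (tolower(m) %in% abbreviations ||
            grepl("^[[:upper:]]$", m) ||                   # initial "K."
            grepl("^[[:alpha:]]\\.([[:alpha:]]\\.)*$", m)) # "e.g." mid-form
          next
      }
    }
    boundaries <- c(boundaries, j)
  }
  if (length(boundaries) == 0L || boundaries[length(boundaries)] < n)
    boundaries <- c(boundaries, n)
  starts <- c(1L, boundaries[-length(boundaries)] + 1L)
  keep <- logical(length(starts))
  a_out <- integer(length(starts)); b_out <- integer(length(starts))
  for (s in seq_along(starts)) {
    a <- starts[s]; b <- boundaries[s]
    while (a <= b && is_space[a]) a <- a + 1L
    while (b >= a && is_space[b]) b <- b - 1L
    if (a > b) next
    keep[s] <- TRUE; a_out[s] <- a; b_out[s] <- b
  }
  a_out <- a_out[keep]; b_out <- b_out[keep]
  data.frame(start = a_out - 1L, end = b_out,
             text = substring(text, a_out, b_out),
             stringsAsFactors = FALSE)
}

#' Whitespace tokenization
#'
#' Tokens are maximal runs of non-whitespace characters; the token count of a
#' sentence is its length in words, the unit every per-thousand density in
#' this package is normalized against.
#'
#' @param sentence Character scalar (or vector; results are concatenated in
#'   order).
#' @return Character vector of tokens.
#' @export
tokenize_whitespace <- function(sentence) {
  if (length(sentence) == 0L) return(character(0))
  toks <- unlist(strsplit(sentence, "[[:space:]]+"), use.names = FALSE)
  toks[nzchar(toks)]
}

#' Count whitespace tokens
#' @param text Character scalar.
#' @return Integer token count.
#' @export
count_tokens <- function(text) length(tokenize_whitespace(text))
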