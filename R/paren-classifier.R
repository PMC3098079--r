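PAREN_CATEGORIES <- c("list_enumerator", "part_of_gene_name",
                      "figure_table_pointer", "citation", "p_value",
                      "data_value", "singular_plural",
                      "abbreviation_or_symbol", "parenthetical_statement",
                      "unknown")

# Cascade precedence: most specific patterns first. P-values precede data
# values because a P-value is a subtype of data string.
PAREN_PRECEDENCE <- c("citation", "figure_table_pointer", "p_value",
                      "list_enumerator", "singular_plural",
                      "part_of_gene_name", "data_value",
                      "abbreviation_or_symbol", "parenthetical_statement")

#' Load the parenthetical classification patterns
#'
#' The regex component of the cascade lives in a versioned plain-text TSV
#' (`category<TAB>regex`) so it is auditable and swappable; structural rules
#' (attachment, token counts, left context) are applied in code.
#'
#' @param path Pattern file; defaults to the file shipped with the package.
#' @return Named list mapping category to a character vector of PCRE
#'   patterns (ORed).
#' @export
load_paren_patterns <- function(path = system.file("extdata",
                                                   "paren_patterns.tsv",
                                                   package = "genreprof")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  cats <- vapply(parts, `[[`, "", 1L)
  pats <- vapply(parts, `[[`, "", 2L)
  split(pats, factor(cats, levels = unique(cats)))
}

matches_any <- function(x, patterns) {
  if (is.null(patterns)) return(FALSE)
  any(vapply(patterns, function(p) grepl(p, x, perl = TRUE), logical(1)))
}

STATEMENT_FUNCTION_WORDS <- c(
  "a", "an", "the", "of", "in", "on", "at", "to", "for", "with", "by",
  "from", "near", "as", "is", "are", "was", "were", "that", "which", "and",
  "or", "but", "not", "no", "this", "these", "than", "see", "data", "but")

#' Classify a parenthesized span
#'
#' Assigns each span to the first matching category in a fixed precedence
#' cascade: citation, figure/table pointer, P-value, list enumerator,
#' singular/plural marker, part of gene name, data value,
#' abbreviation/symbol, parenthetical statement; spans matching nothing are
#' `unknown`. Classification is a pure function of the span content, its
#' left context, and whether the opening parenthesis is attached directly to
#' the preceding word (as in `gene(s)` or `NF-kappa(b)`).
#'
#' @param content Character vector of span contents (parentheses excluded).
#' @param left_context Character vector (recycled) of up to a few tokens of
#'   text preceding the span.
#' @param attached Logical vector (recycled): is the `(` glued to the
#'   preceding word with no intervening space?
#' @param patterns Pattern set from [load_paren_patterns()].
#' @return Character vector of categories, same length as `content`, with a
#'   `mixed` logical attribute flagging spans whose comma/semicolon-separated
#'   pieces match more than one regex category (scored deterministically by
#'   precedence; flagged for diagnostics).
#' @export
classify_paren <- function(content, left_context = "", attached = FALSE,
                           patterns = load_paren_patterns()) {
  n <- length(content)
  left_context <- rep_len(as.character(left_context), n)
  attached <- rep_len(as.logical(attached), n)
  out <- character(n)
  mixed <- logical(n)
  for (i in seq_len(n))
    out[i] <- classify_paren_one(content[i], left_context[i], attached[i],
                                 patterns, function(m) mixed[i] <<- m)
  attr(out, "mixed") <- mixed
  out
}

classify_paren_one <- function(content, left_context, attached, patterns,
                               set_mixed) {
  x <- trimws(content)
  toks <- tokenize_whitespace(x)
  ntok <- length(toks)
  prev_word <- {
    m <- regmatches(left_context,
                    regexpr("[^[:space:]]+$", left_context))
    if (length(m)) gsub("[[:punct:]]+$", "", m) else ""
  }
  # diagnostics: do distinct pieces of the span match distinct categories?
  pieces <- trimws(strsplit(x, "[;,]")[[1]])
  pieces <- pieces[nzchar(pieces)]
  if (length(pieces) > 1L) {
    hit <- unique(unlist(lapply(pieces, function(p) {
      names(patterns)[vapply(patterns, function(ps) matches_any(p, ps),
                             logical(1))]
    })))
    set_mixed(length(hit) > 1L)
  } else set_mixed(FALSE)

  for (cat in PAREN_PRECEDENCE) {
    hit <- switch(cat,
      citation = matches_any(x, patterns$citation),
      figure_table_pointer = matches_any(x, patterns$figure_table_pointer),
      p_value = matches_any(x, patterns$p_value),
      list_enumerator = !attached &&
        matches_any(x, patterns$list_enumerator),
      singular_plural = attached && tolower(x) %in% c("s", "es"),
      part_of_gene_name = attached && ntok == 1L &&
        grepl("^[A-Za-z0-9]{1,3}$", x) && is_gene_like(prev_word),
      data_value = matches_any(x, patterns$data_value),
      abbreviation_or_symbol = is_abbreviation_like(x, toks, left_context),
      parenthetical_statement = ntok >= 3L &&
        any(tolower(gsub("[[:punct:]]+$", "", toks)) %in%
              STATEMENT_FUNCTION_WORDS),
      FALSE)
    if (isTRUE(hit)) return(cat)
  }
  "unknown"
}

# A word like "NF-kappa" or "IL" that a trailing parenthesized letter could
# complete: hyphenated, or carrying >=2 capitals or a digit.
is_gene_like <- function(w) {
  nzchar(w) && (grepl("-", w, fixed = TRUE) ||
                  nchar(gsub("[^A-Z]", "", w)) >= 2L || grepl("[0-9]", w))
}

# Short alphanumeric span (<=3 tokens) with signal of being an abbreviation
# or symbol: capitals/digits inside, and a non-trivial left context whose
# head is either capitalized or an expansion (initial letters matching).
is_abbreviation_like <- function(x, toks, left_context) {
  ntok <- length(toks)
  if (ntok < 1L || ntok > 3L) return(FALSE)
  if (!all(grepl("^[A-Za-z0-9][A-Za-z0-9'-]*$", toks))) return(FALSE)
  if (!grepl("[A-Za-z]", x)) return(FALSE)
  if (!grepl("[A-Z0-9]", x)) return(FALSE)
  ltoks <- tokenize_whitespace(left_context)
  if (length(ltoks) == 0L) return(FALSE)
  TRUE
}

#' Extract outermost parenthesized spans
#'
#' One instance per outermost balanced `( )` pair; nested pairs stay inside
#' the outer instance's content. Unbalanced parentheses are skipped and
#' tallied in the `unbalanced` attribute.
#'
#' @param text Character scalar.
#' @param context_tokens Number of preceding tokens captured as left
#'   context.
#' @return Data frame with `start`, `end` (0-based half-open offsets of the
#'   full span including the parentheses), `content`, `left_context`,
#'   `attached`; attribute `unbalanced` counts skipped lone parentheses.
#' @export
extract_parentheticals <- function(text, context_tokens = 5L) {
  stopifnot(is.character(text), length(text) == 1L)
  pos_open <- as.integer(gregexpr("(", text, fixed = TRUE)[[1]])
  pos_close <- as.integer(gregexpr(")", text, fixed = TRUE)[[1]])
  pos_open <- pos_open[pos_open > 0L]
  pos_close <- pos_close[pos_close > 0L]
  pos <- c(pos_open, pos_close)
  delta <- rep(c(1L, -1L), c(length(pos_open), length(pos_close)))
  ord <- order(pos)
  pos <- pos[ord]; delta <- delta[ord]
  res_start <- integer(0); res_end <- integer(0)
  unbalanced <- 0L
  depth <- 0L; cur_open <- NA_integer_
  for (i in seq_along(pos)) {
    if (delta[i] == 1L) {
      depth <- depth + 1L
      if (depth == 1L) cur_open <- pos[i]
    } else {
      if (depth == 0L) {
        unbalanced <- unbalanced + 1L
      } else {
        depth <- depth - 1L
        if (depth == 0L) {
          res_start <- c(res_start, cur_open)
          res_end <- c(res_end, pos[i])
        }
      }
    }
  }
  unbalanced <- unbalanced + depth  # unclosed opens at end of text
  if (length(res_start) == 0L) {
    out <- data.frame(start = integer(0), end = integer(0),
                      content = character(0), left_context = character(0),
                      attached = logical(0), stringsAsFactors = FALSE)
    attr(out, "unbalanced") <- unbalanced
    return(out)
  }
  before <- substring(text, pmax(1L, res_start - 120L), res_start - 1L)
  lctx <- vapply(strsplit(before, "[[:space:]]+"), function(t) {
    t <- t[nzchar(t)]
    paste(utils::tail(t, context_tokens), collapse = " ")
  }, "")
  prev_char <- substring(text, res_start - 1L, res_start - 1L)
  out <- data.frame(
    start = res_start - 1L, end = res_end,
    content = substring(text, res_start + 1L, res_end - 1L),
    left_context = lctx,
    attached = res_start > 1L & grepl("[[:alnum:]]", prev_char),
    stringsAsFactors = FALSE)
  attr(out, "unbalanced") <- unbalanced
  out
}

#' Parenthesis usage profile of a genre
#'
#' Extracts and classifies every outermost parenthesized span in a genre's
#' text and reports counts per category plus overall incidence per thousand
#' whitespace tokens.
#'
#' @param genre_text Character scalar; must contain at least one token.
#' @param genre Label (e.g. `"abstract"`, `"body"`).
#' @param patterns Pattern set from [load_paren_patterns()].
#' @return A list of class `paren_profile`: `genre`, `counts` (named integer
#'   vector over all categories), `total`, `token_total`,
#'   `incidence_per_thousand`, `unbalanced`.
#' @export
paren_profile <- function(genre_text, genre = "body",
                          patterns = load_paren_patterns()) {
  token_total <- count_tokens(genre_text)
  if (token_total == 0L)
    stop("empty genre text: incidence per thousand tokens is undefined")
  inst <- extract_parentheticals(genre_text)
  cats <- if (nrow(inst) == 0L) character(0) else
    classify_paren(inst$content, inst$left_context, inst$attached, patterns)
  counts <- table(factor(cats, levels = PAREN_CATEGORIES))
  structure(list(
    genre = genre,
    counts = stats::setNames(as.integer(counts), names(counts)),
    total = nrow(inst),
    token_total = token_total,
    incidence_per_thousand = density_per_thousand(nrow(inst), token_total),
    unbalanced = attr(inst, "unbalanced")),
    class = "paren_profile")
}

#' @export
print.paren_profile <- function(x, ...) {
  cat(sprintf("<paren_profile> genre=%s  %d instances in %d tokens (%.2f/1000)\n",
              x$genre, x$total, x$token_total, x$incidence_per_thousand))
  nz <- x$counts[x$counts > 0]
  for (nm in names(nz)) cat(sprintf("  %-24s %6d\n", nm, nz[[nm]]))
  invisible(x)
}
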