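# Strip punctuation off token edges before word-set matching; whitespace
# tokens carry trailing commas and periods that would otherwise hide hits.
strip_edge_punct <- function(tokens) {
  gsub("^[[:punct:]]+|[[:punct:]]+$", "", tokens)
}

count_wordset <- function(tokens, words) {
  sum(tolower(strip_edge_punct(tokens)) %in% words)
}

#' Count coordinating conjunctions
#'
#' Every whole-token instance of *and*, *or*, *but* (case-insensitive,
#' edge punctuation stripped).
#'
#' @param tokens Character vector from [tokenize_whitespace()].
#' @return Integer count.
#' @export
count_coordination <- function(tokens) {
  count_wordset(tokens, c("and", "or", "but"))
}

#' Count negation cues
#'
#' Whole-token instances of *no*, *not*, *neither*.
#'
#' @inheritParams count_coordination
#' @return Integer count.
#' @export
count_negation <- function(tokens) {
  count_wordset(tokens, c("no", "not", "neither"))
}

#' Count passive-voice cues ("...ed by")
#'
#' The default `"token"` mode counts a token ending in *ed* immediately
#' followed by the token *by*; the `"literal"` mode counts every occurrence
#' of the substring `"ed by"` anywhere in the text. Both modes undercount
#' agentless passives and passive conjuncts (*Xed and Yed by*) and can
#' overcount (*the bed by the wall*); the under/overcount applies equally to
#' both genres, so the genre comparison remains valid.
#'
#' @param text Character scalar.
#' @param mode `"token"` (default) or `"literal"`.
#' @return Integer count.
#' @export
count_passives <- function(text, mode = c("token", "literal")) {
  mode <- match.arg(mode)
  if (mode == "literal") {
    m <- gregexpr("ed by", text, fixed = TRUE)[[1]]
    return(sum(m > 0L))
  }
  toks <- tolower(strip_edge_punct(tokenize_whitespace(text)))
  if (length(toks) < 2L) return(0L)
  sum(endsWith(toks[-length(toks)], "ed") & toks[-1L] == "by")
}

#' Default pronoun inventory
#'
#' Third-person neuter/plural pronouns, the anaphors most relevant to
#' coreference in scientific prose. The inventory is an explicit, auditable
#' input: pass your own vector (or a file via [readLines()]) to
#' [count_pronouns()] to change it. Nonreferential *it* ("It is clear
#' that...") is deliberately not excluded.
#'
#' @return Character vector.
#' @export
default_pronouns <- function() {
  c("it", "its", "itself", "they", "them", "their", "themselves")
}

#' Count pronouns
#'
#' @inheritParams count_coordination
#' @param inventory Non-empty character vector of pronoun forms
#'   (lower-case).
#' @return Integer count.
#' @export
count_pronouns <- function(tokens, inventory = default_pronouns()) {
  stopifnot(length(inventory) > 0L)
  count_wordset(tokens, tolower(inventory))
}

#' Per-thousand-token density
#'
#' The package's universal normalization: `count * 1000 / token_total`.
#'
#' @param count Non-negative count.
#' @param token_total Positive token (word) total.
#' @return Numeric density per thousand tokens.
#' @export
density_per_thousand <- function(count, token_total) {
  stopifnot(all(count >= 0))
  if (any(token_total <= 0))
    stop("token_total must be positive: density is undefined on empty text")
  count * 1000 / token_total
}

SURFACE_FEATURES <- c("coordination", "passives", "negation", "pronouns")

#' Surface-feature profile of a genre
#'
#' Counts the four morphosyntactic/discourse cues (coordination, passives,
#' negation, pronominal anaphora) and converts each to a per-thousand-token
#' density.
#'
#' @param genre_text Character scalar with at least one token.
#' @param genre Label.
#' @param pronoun_inventory See [count_pronouns()].
#' @param passive_mode See [count_passives()].
#' @return A data frame of class `feature_profile` with columns `genre`,
#'   `feature`, `count`, `token_total`, `per_thousand`.
#' @export
feature_profile <- function(genre_text, genre = "body",
                            pronoun_inventory = default_pronouns(),
                            passive_mode = "token") {
  token_total <- count_tokens(genre_text)
  if (token_total == 0L) stop("empty genre text")
  toks <- tokenize_whitespace(genre_text)
  counts <- c(coordination = count_coordination(toks),
              passives = count_passives(genre_text, passive_mode),
              negation = count_negation(toks),
              pronouns = count_pronouns(toks, pronoun_inventory))
  structure(data.frame(
    genre = genre, feature = names(counts), count = as.integer(counts),
    token_total = token_total,
    per_thousand = density_per_thousand(as.integer(counts), token_total),
    row.names = NULL, stringsAsFactors = FALSE),
    class = c("feature_profile", "data.frame"))
}
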