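#' Default function-word list
#'
#' A fixed, versioned list of English function words (articles, determiners,
#' prepositions, conjunctions, pronouns, auxiliaries, particles) shipped as
#' a plain-text data file so the readability metric's denominator is
#' auditable. Pass any other character vector to
#' [function_word_percentage()] to substitute your own.
#'
#' @return Character vector of lower-case word forms.
#' @export
default_function_words <- function() {
  path <- system.file("extdata", "function_words.txt", package = "genreprof")
  w <- readLines(path, warn = FALSE)
  w[nzchar(w) & !startsWith(w, "#")]
}

#' Sentence-length statistics
#'
#' Lengths in words (whitespace tokens) with median (midpoint-of-two rule
#' for even counts) and mean.
#'
#' @param sentences Character vector of sentences, or a numeric vector of
#'   precomputed lengths.
#' @return List of class `sentence_stats`: `lengths`, `median`, `mean`, `n`.
#' @export
sentence_length_stats <- function(sentences) {
  if (length(sentences) == 0L) stop("no sentences supplied")
  lengths <- if (is.numeric(sentences)) as.numeric(sentences) else
    vapply(sentences, count_tokens, integer(1), USE.NAMES = FALSE)
  structure(list(lengths = lengths,
                 median = stats::median(lengths),
                 mean = mean(lengths),
                 n = length(lengths)),
            class = "sentence_stats")
}

#' @export
print.sentence_stats <- function(x, ...) {
  cat(sprintf("<sentence_stats> n=%d  median/mean %g/%.2f\n",
              x$n, x$median, x$mean))
  invisible(x)
}

#' Function-word percentage (readability)
#'
#' The percentage of tokens that are function words; readability increases
#' with this percentage.
#'
#' @param tokens Non-empty character vector of tokens.
#' @param function_words Non-empty word list; see
#'   [default_function_words()].
#' @return Percentage in \[0, 100\].
#' @export
function_word_percentage <- function(tokens,
                                     function_words = default_function_words()) {
  if (length(tokens) == 0L) stop("zero tokens: percentage undefined")
  stopifnot(length(function_words) > 0L)
  100 * sum(tolower(strip_edge_punct(tokens)) %in% tolower(function_words)) /
    length(tokens)
}

SUBORDINATORS <- c("because", "although", "though", "since", "unless",
                   "whereas", "while", "if", "until", "that", "whether",
                   "after", "before", "once", "so", "than", "lest",
                   "provided", "whenever", "wherever")
WH_WORDS <- c("who", "whom", "whose", "which", "what", "where", "when",
              "why", "how", "whichever", "whatever", "whoever")
AUXILIARIES <- c("be", "am", "is", "are", "was", "were", "been", "being",
                 "have", "has", "had", "having", "do", "does", "did",
                 "will", "would", "shall", "should", "may", "might",
                 "must", "can", "could")

#' Coarse lexical-class labeling
#'
#' A lexicon-and-suffix heuristic assigning each token one of the classes
#' the syntactic-complexity index counts: `subordinator`, `wh`, `verb`,
#' `noun`, or `other`. Verbs are auxiliaries/modals plus tokens with verbal
#' suffixes; nouns are the remaining content words — a noun-*token* proxy
#' for noun phrases, recorded as such in the output attribute
#' (`noun_proxy`). Swap in any labeler producing the same two-column frame
#' for exact counts.
#'
#' @param tokens Character vector of tokens.
#' @return Data frame (`token`, `class`) with attribute
#'   `noun_proxy = TRUE`.
#' @export
label_lexical_classes <- function(tokens) {
  fw <- default_function_words()
  low <- tolower(strip_edge_punct(tokens))
  cls <- rep("other", length(tokens))
  is_word <- grepl("^[a-z][a-z-]*$", low)
  verbal <- is_word & (low %in% AUXILIARIES |
                         grepl("(ed|ing|ise|ize|ate|ates|ified|ifies)$", low))
  nounish <- is_word & !verbal & !(low %in% fw)
  cls[nounish] <- "noun"
  cls[verbal] <- "verb"
  cls[low %in% WH_WORDS] <- "wh"
  cls[low %in% SUBORDINATORS] <- "subordinator"
  out <- data.frame(token = tokens, class = cls, stringsAsFactors = FALSE)
  attr(out, "noun_proxy") <- TRUE
  out
}

#' Index of Syntactic Complexity
#'
#' `2 x subordinating conjunctions + 2 x WH-pronouns + 1 x verb forms +
#' 1 x noun phrases`, computed from explicit lexical-class labels. The index
#' is additive over concatenated labeled sentences.
#'
#' @param tagged_tokens Data frame with columns `token` and `class` (values
#'   among `subordinator`, `wh`, `verb`, `noun`, `other`), e.g. from
#'   [label_lexical_classes()].
#' @return Non-negative integer score.
#' @export
syntactic_complexity_index <- function(tagged_tokens) {
  if (!is.data.frame(tagged_tokens) ||
      !all(c("token", "class") %in% names(tagged_tokens)))
    stop("unlabeled input: supply a data frame with 'token' and 'class'")
  cls <- tagged_tokens$class
  2L * sum(cls == "subordinator") + 2L * sum(cls == "wh") +
    sum(cls == "verb") + sum(cls == "noun")
}

#' Bin scores into a probability distribution
#'
#' Equal-width bins over the supplied range (default: the data range), as
#' used for the Kullback-Leibler comparison of complexity-score
#' distributions between genres. To compare two samples, bin both with the
#' same `edges` (e.g. computed from their pooled range).
#'
#' @param x Numeric scores.
#' @param bins Number of bins (default 20).
#' @param edges Optional explicit vector of `bins + 1` increasing edges.
#' @return List of class `score_distribution`: `prob` (sums to 1), `edges`,
#'   `metric`.
#' @param metric Optional metric name carried along for labeling.
#' @export
bin_distribution <- function(x, bins = 20L, edges = NULL, metric = "score") {
  stopifnot(length(x) > 0L)
  if (is.null(edges)) {
    r <- range(x)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    edges <- seq(r[1], r[2], length.out = bins + 1L)
  }
  stopifnot(length(edges) >= 2L, !is.unsorted(edges))
  nb <- length(edges) - 1L
  # bins are (e_i, e_{i+1}], with the lowest edge included in bin 1;
  # observations outside the edges are dropped
  idx <- findInterval(x, edges, left.open = TRUE)
  idx[x == edges[1L]] <- 1L
  idx <- idx[idx >= 1L & idx <= nb]
  counts <- tabulate(idx, nbins = nb)
  inside <- sum(counts)
  if (inside == 0L) stop("no observations fall inside the bin edges")
  structure(list(prob = counts / inside, edges = edges, metric = metric),
            class = "score_distribution")
}

#' Kullback-Leibler divergence between binned distributions
#'
#' `sum(p_i * log(p_i / q_i))` over shared bins; `q` is smoothed by adding
#' `epsilon` to every bin (then renormalized) so the divergence is finite,
#' and terms with `p_i = 0` contribute 0. Non-negative; 0 iff `p == q`.
#'
#' @param p,q `score_distribution` objects with identical bin edges (see
#'   [bin_distribution()]).
#' @param base Logarithm base; default natural log.
#' @param epsilon Smoothing constant added to `q`.
#' @return Non-negative numeric divergence.
#' @export
kl_divergence <- function(p, q, base = exp(1), epsilon = 1e-9) {
  stopifnot(inherits(p, "score_distribution"),
            inherits(q, "score_distribution"))
  if (length(p$edges) != length(q$edges) ||
      !isTRUE(all.equal(p$edges, q$edges)))
    stop("mismatched bin edges: distributions are not comparable")
  pi <- p$prob
  qi <- q$prob
  if (any(qi == 0 & pi > 0)) {  # smooth only when q has holes p occupies
    qi <- qi + epsilon
    qi <- qi / sum(qi)
  }
  terms <- ifelse(pi > 0, pi * (log(pi) - log(qi)) / log(base), 0)
  max(0, sum(terms))
}
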