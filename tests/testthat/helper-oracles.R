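# Independent oracles used to cross-check the implementation on small
# instances. These deliberately share no code with the package internals.

# Brute-force span matcher: greedy bipartite matching on exact span
# equality, scanning every gold/predicted pair.
oracle_match_spans <- function(gold, pred) {
  used <- rep(FALSE, nrow(pred))
  tp <- 0L
  for (i in seq_len(nrow(gold))) {
    for (j in seq_len(nrow(pred))) {
      if (used[j]) next
      if (gold$doc_id[i] == pred$doc_id[j] &&
          gold$genre[i] == pred$genre[j] &&
          gold$start[i] == pred$start[j] &&
          gold$end[i] == pred$end[j]) {
        used[j] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  list(TP = tp, FP = nrow(pred) - tp, FN = nrow(gold) - tp)
}

# Brute-force bracket recall: test every candidate span against every gold
# span for a crossing, spelled out over all four interval relations.
oracle_bracket_recall <- function(gold, cand) {
  multi <- function(tr) {
    k <- tr$constituents
    k[k$end - k$start >= 2, , drop = FALSE]
  }
  g <- multi(gold); c_ <- multi(cand)
  compatible <- 0L
  for (i in seq_len(nrow(c_))) {
    cs <- c_$start[i]; ce <- c_$end[i]
    crosses <- FALSE
    for (j in seq_len(nrow(g))) {
      gs <- g$start[j]; ge <- g$end[j]
      overlap <- max(cs, gs) < min(ce, ge)
      contains <- (cs <= gs && ge <= ce) || (gs <= cs && ce <= ge)
      if (overlap && !contains) { crosses <- TRUE; break }
    }
    if (!crosses) compatible <- compatible + 1L
  }
  compatible / nrow(g)
}

# Random binary bracketing over n words, emitted as a PTB string.
random_ptb_string <- function(n, tags = NULL) {
  if (is.null(tags)) tags <- sample(c("NN", "VB", "DT", "JJ"), n,
                                    replace = TRUE)
  words <- paste0("w", seq_len(n))
  build <- function(lo, hi) {
    if (lo == hi) return(sprintf("(%s %s)", tags[lo], words[lo]))
    split <- if (hi - lo == 1) lo else sample(lo:(hi - 1L), 1L)
    sprintf("(X %s %s)", build(lo, split), build(split + 1L, hi))
  }
  build(1L, n)
}

# Random span sets for matcher property tests: up to max_spans
# non-overlapping token-aligned spans per document.
random_span_set <- function(n_docs = 2L, max_spans = 10L) {
  rows <- NULL
  for (d in seq_len(n_docs)) {
    k <- sample.int(max_spans, 1L)
    starts <- sort(sample.int(200L, k)) * 10L
    ends <- starts + sample.int(9L, k, replace = TRUE)
    rows <- rbind(rows, data.frame(doc_id = paste0("d", d),
                                   genre = "body", start = starts,
                                   end = ends, stringsAsFactors = FALSE))
  }
  mention_set(rows$doc_id, rows$genre, rows$start, rows$end,
              text = "x", class = "gene")
}

# Small corpus spec scaled for unit tests: same planted rates as the
# defaults, fewer and shorter documents.
small_spec <- function(n_docs = 3L, seed = 1L, body_sentences = 30L) {
  sp <- genre_spec(n_docs = n_docs, seed = seed)
  sp$body$sentences_per_doc <- body_sentences
  sp
}
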