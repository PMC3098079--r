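# Validate one mention set: within each (doc_id, genre), spans must not
# overlap (and hence carry no duplicates).
check_no_overlap <- function(spans, label) {
  key <- paste(spans$doc_id, spans$genre)
  for (k in unique(key)) {
    s <- spans[key == k, , drop = FALSE]
    s <- s[order(s$start, s$end), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
      stop("overlapping or duplicate spans within the ", label,
           " set for ", k)
  }
  invisible(TRUE)
}

#' Match predicted spans against gold spans
#'
#' Exact matching: a predicted span is a true positive iff a gold span with
#' the same (doc_id, genre, start, end) exists; each gold span matches at
#' most one prediction. Unmatched predictions are false positives, unmatched
#' gold spans false negatives. By construction `TP + FN` equals the gold
#' span count and `TP + FP` the predicted span count.
#'
#' @param gold,predicted `mention_set` objects over the same documents.
#' @param mode Matching protocol; only `"exact"` is implemented.
#' @return List of class `confusion_counts`: `TP`, `FP`, `FN`.
#' @export
match_spans <- function(gold, predicted, mode = c("exact")) {
  mode <- match.arg(mode)
  check_no_overlap(gold, "gold")
  check_no_overlap(predicted, "predicted")
  gk <- paste(gold$doc_id, gold$genre, gold$start, gold$end, sep = "\r")
  pk <- paste(predicted$doc_id, predicted$genre, predicted$start,
              predicted$end, sep = "\r")
  tp <- sum(pk %in% gk)
  structure(list(TP = tp, FP = length(pk) - tp, FN = length(gk) - tp),
            class = "confusion_counts")
}

#' Precision, recall and F-measure from confusion counts
#'
#' `P = TP/(TP+FP)`; `R = TP/gold_total` when an explicit gold total is
#' supplied, else `TP/(TP+FN)`; `F = 2PR/(P+R)`. Zero denominators yield
#' `NA` (undefined), never 0. Values are unrounded; rounding (3 decimals)
#' happens only in the print method.
#'
#' @param counts A `confusion_counts` object, or a list with `TP`, `FP`,
#'   `FN`.
#' @param gold_total Optional explicit recall denominator, used when the
#'   annotation total is known independently of the matcher's `TP + FN`.
#' @return List of class `prf_result`: `precision`, `recall`, `f_measure`,
#'   plus the counts and denominator used.
#' @export
prf <- function(counts, gold_total = NULL) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  denom <- if (!is.null(gold_total)) {
    stopifnot(gold_total > 0)
    gold_total
  } else tp + fn
  recall <- if (denom > 0) tp / denom else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(precision = precision, recall = recall, f_measure = f,
                 TP = tp, FP = fp, FN = fn, recall_denominator = denom),
            class = "prf_result")
}

#' @export
print.prf_result <- function(x, ...) {
  cat(sprintf("P=%.3f R=%.3f F=%.3f  (TP=%d FP=%d FN=%d)\n",
              x$precision, x$recall, x$f_measure, x$TP, x$FP, x$FN))
  invisible(x)
}

#' Read a Penn-Treebank-style bracketed tree
#'
#' Parses one bracketing like
#' `(S (NP (DT The) (NN dog)) (VP (VBD ran)))` into a `bracketed_tree`:
#' the word sequence, the per-word part-of-speech tags, and the constituent
#' table (label, start, end as 0-based half-open word indices).
#'
#' @param line Character scalar holding one bracketed tree.
#' @return List of class `bracketed_tree`: `words`, `tags`, `constituents`
#'   (data frame `label`, `start`, `end`).
#' @export
read_ptb_tree <- function(line) {
  toks <- regmatches(line, gregexpr("\\(|\\)|[^()\\s]+", line,
                                    perl = TRUE))[[1]]
  words <- character(0); tags <- character(0)
  lab <- character(0); st <- integer(0); en <- integer(0)
  stack_label <- character(0); stack_start <- integer(0)
  i <- 1L; n <- length(toks)
  expect_label <- FALSE
  while (i <= n) {
    t <- toks[i]
    if (t == "(") {
      if (i + 1L > n || toks[i + 1L] %in% c("(", ")"))
        stop("malformed bracketing: '(' without a label at token ", i)
      lab_i <- toks[i + 1L]
      if (i + 2L <= n && toks[i + 2L] != "(" && toks[i + 2L] != ")") {
        # preterminal: (TAG word)
        if (i + 3L > n || toks[i + 3L] != ")")
          stop("malformed preterminal at token ", i)
        words <- c(words, toks[i + 2L])
        tags <- c(tags, lab_i)
        i <- i + 4L
      } else {
        stack_label <- c(stack_label, lab_i)
        stack_start <- c(stack_start, length(words))
        i <- i + 2L
      }
    } else if (t == ")") {
      if (length(stack_label) == 0L)
        stop("malformed bracketing: unmatched ')' at token ", i)
      k <- length(stack_label)
      lab <- c(lab, stack_label[k])
      st <- c(st, stack_start[k])
      en <- c(en, length(words))
      stack_label <- stack_label[-k]; stack_start <- stack_start[-k]
      i <- i + 1L
    } else {
      stop("unexpected token '", t, "' outside brackets")
    }
  }
  if (length(stack_label) > 0L) stop("malformed bracketing: unclosed '('")
  if (length(words) == 0L) stop("tree contains no words")
  structure(list(words = words, tags = tags,
                 constituents = data.frame(label = lab, start = st, end = en,
                                           stringsAsFactors = FALSE)),
            class = "bracketed_tree")
}

#' Serialize word-span constituents for display
#' @export
print.bracketed_tree <- function(x, ...) {
  cat("<bracketed_tree> ", paste(x$words, collapse = " "), "\n", sep = "")
  cat("  ", nrow(x$constituents), " constituents\n", sep = "")
  invisible(x)
}

#' Read bracketed trees from a file, one per line
#' @param path File path.
#' @return List of `bracketed_tree` objects.
#' @export
read_ptb_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, read_ptb_tree)
}

# Two half-open spans cross iff they overlap but neither contains the other.
spans_cross <- function(a1, a2, b1, b2) {
  (a1 < b1 & b1 < a2 & a2 < b2) | (b1 < a1 & a1 < b2 & b2 < a2)
}

#' Bracket recall
#'
#' Unlabeled, compatibility-based recall: a candidate constituent is
#' compatible iff it does not cross any gold constituent boundary (a span is
#' incompatible when it is neither a substring nor a superstring of every
#' gold span it overlaps). Single-word constituents are excluded from both
#' counts. The value is the number of compatible candidate constituents
#' divided by the number of gold constituents — note this differs from
#' standard labeled PARSEVAL recall, and a candidate parse with more
#' non-crossing brackets than the gold tree can score above 1.
#'
#' @param gold,candidate `bracketed_tree` objects over the same word
#'   sequence.
#' @return Numeric recall.
#' @export
bracket_recall <- function(gold, candidate) {
  stopifnot(inherits(gold, "bracketed_tree"),
            inherits(candidate, "bracketed_tree"))
  if (!identical(gold$words, candidate$words))
    stop("gold and candidate trees have different word sequences")
  g <- gold$constituents
  g <- g[g$end - g$start >= 2L, , drop = FALSE]
  c_ <- candidate$constituents
  c_ <- c_[c_$end - c_$start >= 2L, , drop = FALSE]
  if (nrow(g) == 0L) stop("gold tree has no multi-word constituents")
  compatible <- vapply(seq_len(nrow(c_)), function(i)
    !any(spans_cross(c_$start[i], c_$end[i], g$start, g$end)),
    logical(1))
  sum(compatible) / nrow(g)
}

#' Part-of-speech tag accuracy
#'
#' Fraction of words whose candidate tag equals the gold tag.
#'
#' @param gold_tags,candidate_tags Equal-length character vectors.
#' @return Value in \[0, 1\].
#' @export
tag_accuracy <- function(gold_tags, candidate_tags) {
  if (length(gold_tags) != length(candidate_tags))
    stop("tag sequences differ in length")
  if (length(gold_tags) == 0L) stop("empty tag sequences")
  mean(gold_tags == candidate_tags)
}
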