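# Coerce the run_full_analysis input into a list of sectioned_documents.
as_document_list <- function(corpus) {
  if (inherits(corpus, "synthetic_corpus")) return(corpus$documents)
  if (inherits(corpus, "sectioned_document")) return(list(corpus))
  if (is.character(corpus) && length(corpus) == 1L && dir.exists(corpus)) {
    paths <- list.files(corpus, pattern = "\\.(xml|txt)$",
                        full.names = TRUE)
    if (length(paths) == 0L) stop("no .xml or .txt documents in ", corpus)
    return(lapply(paths, read_document))
  }
  if (is.list(corpus) &&
      all(vapply(corpus, inherits, logical(1), "sectioned_document")))
    return(corpus)
  stop("corpus must be a synthetic_corpus, a sectioned_document, a list ",
       "of them, or a directory path")
}

#' Run the full genre-comparison analysis
#'
#' Orchestrates every stage of the abstract-versus-body comparison over a
#' corpus of sectioned documents: sentence-length statistics per section
#' with a pairwise significance matrix, parenthesis usage profiles,
#' surface-feature densities with normality-gated significance tests,
#' complexity and readability metrics with a Kullback-Leibler comparison,
#' entity-mention density reports (from gold annotations and/or a drug
#' dictionary), span-matching precision/recall/F when predictions are
#' supplied, and a summary of which features were normally distributed.
#' Stages whose inputs are missing are skipped with a warning, not aborted.
#'
#' @param corpus A `synthetic_corpus`, a list of [sectioned_document]s, a
#'   single document, or a directory containing `.xml`/`.txt` documents.
#' @param gold_mentions Optional gold `mention_set`; defaults to the
#'   corpus's own gold set when `corpus` is synthetic.
#' @param predicted_mentions Optional predicted `mention_set`; enables the
#'   PRF stage.
#' @param drug_dictionary Optional raw drug dictionary (character vector);
#'   filtered with [filter_dictionary()] and matched against both genres.
#' @param include_title Include the title in the abstract genre for
#'   feature/density stages (sentence-length statistics always exclude it,
#'   since titles are not sentences).
#' @param include_bibliography Keep bibliography sections in the body
#'   genre.
#' @param alpha Significance level for adjusted p-values (default 0.01).
#' @param bins Bin count for the complexity-score distributions.
#' @param gold_total Optional named numeric vector of explicit recall
#'   denominators per genre for the PRF stage.
#' @param out_dir Optional directory; when given, every table is written as
#'   TSV plus a human-readable `report.md`.
#' @return List of class `genre_report` with elements `sentence_lengths`,
#'   `section_matrix`, `paren_profiles`, `feature_table`,
#'   `feature_comparisons`, `complexity`, `mention_density`,
#'   `drug_matches`, `prf`, `normality_summary`, `log`.
#' @export
run_full_analysis <- function(corpus, gold_mentions = NULL,
                              predicted_mentions = NULL,
                              drug_dictionary = NULL,
                              include_title = TRUE,
                              include_bibliography = FALSE,
                              alpha = 0.01, bins = 20L,
                              gold_total = NULL, out_dir = NULL) {
  docs <- as_document_list(corpus)
  if (is.null(gold_mentions) && inherits(corpus, "synthetic_corpus"))
    gold_mentions <- corpus$mentions
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("documents: %d", length(docs))

  ## genre texts per document
  parts <- lapply(docs, partition_genres, include_title = include_title,
                  include_bibliography = include_bibliography)
  doc_ids <- vapply(docs, function(d) d$doc_id, "")
  abstract_texts <- stats::setNames(
    vapply(parts, `[[`, "", "abstract_text"), doc_ids)
  body_texts <- stats::setNames(
    vapply(parts, `[[`, "", "body_text"), doc_ids)
  genre_texts <- list(abstract = abstract_texts, body = body_texts)
  has_genre <- vapply(genre_texts, function(g) any(nzchar(trimws(g))),
                      logical(1))

  ## stage 1: sentence lengths per section kind + genre
  sent_by_section <- list()
  for (d in docs) for (i in seq_len(nrow(d$sections))) {
    kind <- d$sections$kind[i]
    if (kind %in% c("title", "bibliography")) next
    sents <- segment_sentences(d$sections$text[i])$text
    if (length(sents))
      sent_by_section[[kind]] <- c(sent_by_section[[kind]],
                                   vapply(sents, count_tokens, integer(1),
                                          USE.NAMES = FALSE))
  }
  sentence_lengths <- do.call(rbind, lapply(names(sent_by_section),
    function(k) {
      s <- sentence_length_stats(sent_by_section[[k]])
      data.frame(section = k, n_sentences = s$n, median = s$median,
                 mean = s$mean, stringsAsFactors = FALSE)
    }))
  eligible <- names(sent_by_section)[
    vapply(sent_by_section, length, integer(1)) >= 3L]
  section_matrix <- NULL
  if (length(eligible) >= 2L) {
    section_matrix <- pairwise_section_matrix(sent_by_section[eligible],
                                              alpha = alpha)
  } else note("section matrix skipped: fewer than 2 sections with >= 3 sentences")
  note("sentence lengths: %d sections", length(sent_by_section))

  ## stage 2: parenthesis profiles
  paren_profiles <- list()
  for (g in names(genre_texts)[has_genre])
    paren_profiles[[g]] <- paren_profile(
      paste(genre_texts[[g]], collapse = "\n"), genre = g)
  note("paren profiles: %s", paste(names(paren_profiles), collapse = ", "))

  ## stage 3: surface features, totals + per-document comparisons
  feature_table <- do.call(rbind, lapply(names(genre_texts)[has_genre],
    function(g) feature_profile(paste(genre_texts[[g]], collapse = "\n"),
                                genre = g)))
  feature_comparisons <- NULL
  normality_summary <- NULL
  if (all(has_genre) && length(docs) >= 3L) {
    per_doc <- lapply(genre_texts, function(gt) {
      gt <- gt[nzchar(trimws(gt))]
      sapply(SURFACE_FEATURES, function(f) {
        vapply(gt, function(x) {
          fp <- feature_profile(x)
          fp$per_thousand[fp$feature == f]
        }, numeric(1))
      })
    })
    m <- length(SURFACE_FEATURES)
    feature_comparisons <- lapply(SURFACE_FEATURES, function(f)
      compare_samples(per_doc$abstract[, f], per_doc$body[, f],
                      feature = f, m = m))
    names(feature_comparisons) <- SURFACE_FEATURES
    normality_summary <- data.frame(
      feature = SURFACE_FEATURES,
      normal_abstract = vapply(SURFACE_FEATURES, function(f)
        normality_gate(per_doc$abstract[, f])$pass, logical(1)),
      normal_body = vapply(SURFACE_FEATURES, function(f)
        normality_gate(per_doc$body[, f])$pass, logical(1)),
      test_used = vapply(feature_comparisons, `[[`, "", "test"),
      p_adjusted = vapply(feature_comparisons, `[[`, 0, "p_adjusted"),
      significant = vapply(feature_comparisons, function(x)
        x$p_adjusted < alpha, logical(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  } else note("feature comparison skipped: need both genres and >= 3 docs")

  ## stage 4: complexity and readability
  complexity <- NULL
  if (all(has_genre)) {
    isc_scores <- lapply(genre_texts, function(gt) {
      sents <- unlist(lapply(gt[nzchar(trimws(gt))], function(x)
        segment_sentences(x)$text), use.names = FALSE)
      vapply(sents, function(s) syntactic_complexity_index(
        label_lexical_classes(tokenize_whitespace(s))), numeric(1),
        USE.NAMES = FALSE)
    })
    pooled <- range(unlist(isc_scores))
    if (pooled[1] == pooled[2]) pooled <- pooled + c(-0.5, 0.5)
    edges <- seq(pooled[1], pooled[2], length.out = bins + 1L)
    pa <- bin_distribution(isc_scores$abstract, edges = edges,
                           metric = "syntactic_complexity_index")
    pb <- bin_distribution(isc_scores$body, edges = edges,
                           metric = "syntactic_complexity_index")
    complexity <- list(
      function_word_pct = vapply(genre_texts, function(gt)
        function_word_percentage(
          tokenize_whitespace(paste(gt, collapse = " "))), numeric(1)),
      isc = isc_scores,
      kl_abstract_vs_body = kl_divergence(pa, pb),
      kl_body_vs_abstract = kl_divergence(pb, pa),
      noun_proxy = TRUE)
    note("complexity: KL(abstract||body) = %.4g",
         complexity$kl_abstract_vs_body)
  }

  ## stage 5: mention densities
  word_totals <- vapply(genre_texts, function(gt)
    count_tokens(paste(gt, collapse = " ")), integer(1))
  doc_counts <- vapply(genre_texts, function(gt)
    sum(nzchar(trimws(gt))), integer(1))
  mention_density <- NULL
  if (!is.null(gold_mentions) && nrow(gold_mentions) > 0L) {
    ok <- word_totals > 0
    mention_density <- density_report(
      gold_mentions[gold_mentions$genre %in% names(word_totals)[ok], ,
                    drop = FALSE],
      word_totals[ok], doc_counts[ok])
  } else note("mention density skipped: no annotations supplied")

  ## stage 6: dictionary drug matching
  drug_matches <- NULL
  if (!is.null(drug_dictionary)) {
    dict <- filter_dictionary(drug_dictionary)
    hits <- list()
    for (g in names(genre_texts)[has_genre])
      for (doc_id in names(genre_texts[[g]])) {
        h <- dictionary_match(genre_texts[[g]][[doc_id]], dict,
                              doc_id = doc_id, genre = g)
        if (nrow(h)) hits[[length(hits) + 1L]] <- h
      }
    matched <- if (length(hits)) do.call(rbind, hits) else mention_set()
    drug_matches <- list(
      dictionary_kept = length(dict),
      removed = attr(dict, "removed"),
      mentions = matched,
      density = if (nrow(matched) > 0L)
        density_report(matched, word_totals[has_genre],
                       doc_counts[has_genre]) else NULL)
    note("drug matching: %d mentions from %d dictionary entries",
         nrow(matched), length(dict))
  }

  ## stage 7: PRF against predictions
  prf_results <- NULL
  if (!is.null(predicted_mentions) && !is.null(gold_mentions)) {
    prf_results <- list()
    for (g in unique(gold_mentions$genre)) {
      gg <- gold_mentions[gold_mentions$genre == g, , drop = FALSE]
      pg <- predicted_mentions[predicted_mentions$genre == g, ,
                               drop = FALSE]
      counts <- match_spans(gg, pg)
      gt <- if (!is.null(gold_total) && g %in% names(gold_total))
        gold_total[[g]] else NULL
      prf_results[[g]] <- prf(counts, gold_total = gt)
    }
    note("PRF: %s", paste(names(prf_results), collapse = ", "))
  } else if (!is.null(predicted_mentions))
    note("PRF skipped: predictions supplied without gold annotations")

  report <- structure(list(
    sentence_lengths = sentence_lengths,
    section_matrix = section_matrix,
    paren_profiles = paren_profiles,
    feature_table = feature_table,
    feature_comparisons = feature_comparisons,
    complexity = complexity,
    mention_density = mention_density,
    drug_matches = drug_matches,
    prf = prf_results,
    normality_summary = normality_summary,
    log = log), class = "genre_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.genre_report <- function(x, ...) {
  cat("<genre_report>\n")
  for (line in x$log) cat("  ", line, "\n", sep = "")
  invisible(x)
}

# Persist every table of a report bundle as TSV plus a markdown digest, so
# each reported number is recomputable from the written intermediates.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, name) utils::write.table(
    d, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  md <- c("# Genre comparison report", "")
  if (!is.null(report$sentence_lengths)) {
    tsv(report$sentence_lengths, "sentence_lengths.tsv")
    md <- c(md, "## Sentence lengths (words) per section", "",
            paste0("- ", report$sentence_lengths$section, ": median ",
                   report$sentence_lengths$median, ", mean ",
                   round(report$sentence_lengths$mean, 2)), "")
  }
  if (!is.null(report$section_matrix))
    tsv(report$section_matrix$comparisons, "section_comparisons.tsv")
  if (length(report$paren_profiles)) {
    pp <- do.call(rbind, lapply(report$paren_profiles, function(p)
      data.frame(genre = p$genre, category = names(p$counts),
                 count = p$counts,
                 per_thousand = density_per_thousand(p$counts,
                                                    p$token_total),
                 row.names = NULL, stringsAsFactors = FALSE)))
    tsv(pp, "paren_profile.tsv")
    md <- c(md, "## Parenthesis usage", "",
            vapply(report$paren_profiles, function(p)
              sprintf("- %s: %d instances, %.1f per thousand tokens",
                      p$genre, p$total, p$incidence_per_thousand), ""), "")
  }
  if (!is.null(report$feature_table)) {
    tsv(report$feature_table, "features.tsv")
    md <- c(md, "## Surface-feature densities (per thousand tokens)", "",
            sprintf("- %s/%s: %.2f", report$feature_table$genre,
                    report$feature_table$feature,
                    report$feature_table$per_thousand), "")
  }
  if (!is.null(report$normality_summary)) {
    tsv(report$normality_summary, "normality_summary.tsv")
    md <- c(md, "## Feature significance", "",
            sprintf("- %s: %s, adjusted p = %.3g%s",
                    report$normality_summary$feature,
                    report$normality_summary$test_used,
                    report$normality_summary$p_adjusted,
                    ifelse(report$normality_summary$significant,
                           " (significant)", "")), "")
  }
  if (!is.null(report$mention_density)) {
    tsv(report$mention_density, "mention_density.tsv")
    md <- c(md, "## Mention densities (per thousand words)", "",
            sprintf("- %s/%s: %.2f (%d docs mentioning)",
                    report$mention_density$genre,
                    report$mention_density$class,
                    report$mention_density$per_thousand,
                    report$mention_density$docs_mentioning), "")
  }
  if (!is.null(report$drug_matches) &&
      !is.null(report$drug_matches$density))
    tsv(report$drug_matches$density, "drug_density.tsv")
  if (!is.null(report$prf)) {
    pr <- do.call(rbind, lapply(names(report$prf), function(g) {
      x <- report$prf[[g]]
      data.frame(genre = g, precision = x$precision, recall = x$recall,
                 f_measure = x$f_measure, TP = x$TP, FP = x$FP, FN = x$FN,
                 stringsAsFactors = FALSE)
    }))
    tsv(pr, "prf.tsv")
    md <- c(md, "## Tagger scoring", "",
            sprintf("- %s: P=%.3f R=%.3f F=%.3f", pr$genre, pr$precision,
                    pr$recall, pr$f_measure), "")
  }
  if (!is.null(report$complexity))
    md <- c(md, "## Complexity", "",
            sprintf("- function-word %%: abstract %.2f, body %.2f",
                    report$complexity$function_word_pct[["abstract"]],
                    report$complexity$function_word_pct[["body"]]),
            sprintf("- KL(abstract||body) of complexity scores: %.4g",
                    report$complexity$kl_abstract_vs_body), "")
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
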