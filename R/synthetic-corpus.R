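# Filler vocabulary for synthetic sentences: mouse-genomics-flavored content
# words chosen so that no filler collides with anything the pipeline counts
# (no coordinators, negators, pronouns, "by", nothing ending in "ed", no
# planted entity names, no abbreviation-list words).
FILLER_VOCAB <- c(
  "protein", "expression", "signal", "pathway", "tissue", "sample",
  "mouse", "strain", "locus", "marker", "region", "allele", "variant",
  "assay", "result", "growth", "factor", "receptor", "membrane",
  "nucleus", "culture", "genome", "sequence", "analysis", "pattern",
  "cluster", "profile", "trait", "model", "tumor", "liver", "brain",
  "kidney", "muscle", "neuron", "cortex", "enzyme", "kinase", "ligand",
  "domain", "complex", "vector", "plasmid", "promoter", "exon", "intron",
  "codon", "peptide", "antibody", "serum", "plasma", "glucose", "insulin",
  "lipid", "phenotype", "genotype", "linkage", "mapping", "litter",
  "embryo", "development", "stage", "response", "treatment", "dosage",
  "level", "ratio", "index", "cohort", "replicate", "gradient", "matrix")

# One exemplar-shaped template per parenthetical category. "attached"
# templates are glued onto an existing token; the rest are inserted after
# one, adding their own whitespace tokens.
PAREN_TEMPLATES <- list(
  list_enumerator = list(text = "(A)", attached = FALSE),
  part_of_gene_name = list(text = "NF-kappa(b)", attached = TRUE,
                           replaces = TRUE),
  figure_table_pointer = list(text = "(Fig. 2)", attached = FALSE),
  citation = list(text = "(Fambrough et al. 1999)", attached = FALSE),
  p_value = list(text = "(P < .001)", attached = FALSE),
  data_value = list(text = "(h2 = 0.39)", attached = FALSE),
  singular_plural = list(text = "(s)", attached = TRUE, replaces = FALSE),
  abbreviation_or_symbol = list(text = "(QTLs)", attached = FALSE),
  parenthetical_statement = list(text = "(LRS of 17.5 near D10Mit186)",
                                 attached = FALSE),
  unknown = list(text = "(wholly unclassifiable miscellany)",
                 attached = FALSE))

MENTION_SURFACE_FORMS <- list(
  gene = c("Gata4", "Sox9", "Trp53", "Brca1", "Myod1"),
  mutation = c("A123T", "G45R", "L206P"),
  drug = c("aspirin", "warfarin", "ibuprofen", "metformin", "tamoxifen"),
  disease = c("glaucoma", "fibrosis", "carcinoma", "dystrophy"))

#' Synthetic drug dictionary
#'
#' A small dictionary in the one-name-per-line style of compound-database
#' exports, containing the names the synthetic corpus plants plus decoy
#' entries that the filtering rules must remove. Synthetic: not derived from
#' any real drug database.
#'
#' @return Character vector of raw (unfiltered) entries.
#' @export
synthetic_drug_dictionary <- function() {
  c(MENTION_SURFACE_FORMS$drug,
    "folic acid",
    "1,2-bis(2-aminophenoxy)ethane",  # special characters -> removed
    "lysine",                         # amino acid -> removed
    "water",                          # general English -> removed
    "gold")                           # shorter than five characters -> removed
}

# Per-genre parameter block. Rates are per thousand whitespace tokens.
genre_params <- function(n_docs, sentences_per_doc, length_meanlog,
                         length_sdlog, paren_per_thousand, paren_mixture,
                         feature_rates, mention_rates) {
  stopifnot(abs(sum(paren_mixture) - 1) < 1e-8, all(paren_mixture >= 0),
            all(feature_rates >= 0), all(mention_rates >= 0))
  list(n_docs = n_docs, sentences_per_doc = sentences_per_doc,
       length_meanlog = length_meanlog, length_sdlog = length_sdlog,
       paren_per_thousand = paren_per_thousand,
       paren_mixture = paren_mixture,
       feature_rates = feature_rates, mention_rates = mention_rates)
}

#' Two-genre corpus specification
#'
#' Defaults emulate the statistical structure of a 97-article
#' mouse-genomics corpus: right-skewed (lognormal) sentence lengths with
#' genre means near 26 (abstracts) and 30 (bodies) words, parenthesis
#' incidence 10 vs 28 per thousand tokens with genre-specific category
#' mixtures, surface-feature rates per thousand tokens of 36.2/37.5
#' (coordination), 3.7/4.3 (passives), 3.8/5.3 (negation), 5.3/3.98
#' (pronouns), and mention densities of 61/47 (genes), 0.08/0.28
#' (mutations), 2.97/2.21 (drugs), 4.1/3.74 (diseases). Override any block
#' to scale the corpus or plant different conditions.
#'
#' @param n_docs Number of documents.
#' @param abstract,body Per-genre parameter blocks; see the source of
#'   [genre_spec()] for the field list (`sentences_per_doc`,
#'   `length_meanlog`, `length_sdlog`, `paren_per_thousand`,
#'   `paren_mixture`, `feature_rates`, `mention_rates`).
#' @param seed Integer seed; a fixed seed makes [generate_corpus()] output
#'   byte-identical across runs.
#' @return List of class `genre_spec`.
#' @export
genre_spec <- function(n_docs = 97L,
                       abstract = NULL, body = NULL, seed = 1L) {
  cats <- PAREN_CATEGORIES
  mix_abstract <- stats::setNames(c(3, 0, 0, 0, 2, 11, 2, 124, 23, 61) / 226,
                                  c("list_enumerator", "part_of_gene_name",
                                    "figure_table_pointer", "citation",
                                    "p_value", "data_value",
                                    "singular_plural",
                                    "abbreviation_or_symbol",
                                    "parenthetical_statement", "unknown"))
  mix_body <- stats::setNames(
    c(1399, 0, 2825, 172, 146, 2116, 33, 1862, 3453, 4831) / 16837,
    names(mix_abstract))
  if (is.null(abstract))
    abstract <- genre_params(
      n_docs = n_docs, sentences_per_doc = 9L,
      length_meanlog = 3.197, length_sdlog = 0.35,
      paren_per_thousand = 10,
      paren_mixture = mix_abstract[cats],
      feature_rates = c(coordination = 36.2, passives = 3.7,
                        negation = 3.8, pronouns = 5.3),
      mention_rates = c(gene = 61, mutation = 0.08, drug = 2.97,
                        disease = 4.1))
  if (is.null(body))
    body <- genre_params(
      n_docs = n_docs, sentences_per_doc = 205L,
      length_meanlog = 3.341, length_sdlog = 0.35,
      paren_per_thousand = 28,
      paren_mixture = mix_body[cats],
      feature_rates = c(coordination = 37.5, passives = 4.3,
                        negation = 5.3, pronouns = 3.98),
      mention_rates = c(gene = 47, mutation = 0.28, drug = 2.21,
                        disease = 3.74))
  abstract$n_docs <- n_docs; body$n_docs <- n_docs
  structure(list(n_docs = n_docs, abstract = abstract, body = body,
                 seed = as.integer(seed)),
            class = "genre_spec")
}

# Replace NA mixture entries with 0 and renormalize a named mixture onto
# the full category set.
full_mixture <- function(mix) {
  out <- stats::setNames(numeric(length(PAREN_CATEGORIES)), PAREN_CATEGORIES)
  out[names(mix)] <- ifelse(is.na(mix), 0, mix)
  out / sum(out)
}

# Generate one genre's token slots for one document. Returns the slot
# character vector (some slots hold multi-token strings), the planted
# tallies, and mention records (slot index + surface form + class).
generate_genre_doc <- function(p) {
  n_sent <- p$sentences_per_doc
  lens <- pmax(3L, as.integer(round(stats::rlnorm(n_sent, p$length_meanlog,
                                                  p$length_sdlog))))
  total0 <- sum(lens)
  sent_id <- rep.int(seq_len(n_sent), lens)
  pos <- sequence(lens)
  is_initial <- pos == 1L
  is_final <- pos == lens[sent_id]
  slots <- sample(FILLER_VOCAB, total0, replace = TRUE)
  plain <- !is_initial & !is_final
  mix <- full_mixture(p$paren_mixture)
  tmpl_extra <- vapply(PAREN_TEMPLATES, function(t)
    if (isTRUE(t$attached)) 0L else length(tokenize_whitespace(t$text)),
    integer(1))[names(mix)]
  mean_extra <- sum(mix * tmpl_extra)
  # choose the parenthetical count against the post-insertion token total so
  # the measured incidence is unbiased despite the tokens insertions add
  t_est <- total0 / max(1e-9, 1 - p$paren_per_thousand * mean_extra / 1000)
  n_par <- stats::rpois(1L, p$paren_per_thousand * t_est / 1000)
  paren_counts <- stats::setNames(integer(length(mix)), names(mix))
  if (n_par > 0L) {
    cats <- sample(names(mix), n_par, replace = TRUE, prob = mix)
    paren_counts <- stats::setNames(
      as.integer(table(factor(cats, levels = names(mix)))), names(mix))
    for (cat in cats) {
      avail <- which(plain)
      if (length(avail) == 0L)
        stop("contradictory spec: parenthetical rate exceeds capacity")
      i <- if (length(avail) == 1L) avail else sample(avail, 1L)
      t <- PAREN_TEMPLATES[[cat]]
      if (isTRUE(t$attached)) {
        slots[i] <- if (isTRUE(t$replaces)) t$text
        else paste0(slots[i], t$text)
      } else {
        slots[i] <- paste(slots[i], t$text)
      }
      plain[i] <- FALSE
    }
  }
  total1 <- total0 + if (n_par > 0L)
    sum(tmpl_extra[cats]) else 0L
  # surface features: replace plain filler slots so the token total is
  # unchanged and planted counts are exact
  feature_counts <- stats::setNames(integer(length(p$feature_rates)),
                                    names(p$feature_rates))
  feature_words <- list(coordination = c("and", "or", "but"),
                        negation = c("no", "not", "neither"),
                        pronouns = c("it", "they", "them", "their"))
  for (f in names(p$feature_rates)) {
    k <- stats::rpois(1L, p$feature_rates[[f]] * total1 / 1000)
    feature_counts[[f]] <- k
    if (k == 0L) next
    if (f == "passives") {
      placed <- 0L
      guard <- 0L
      while (placed < k) {
        ok <- which(plain[-length(plain)] & c(plain[-1L]) &
                      sent_id[-length(sent_id)] == c(sent_id[-1L]))
        if (length(ok) == 0L || (guard <- guard + 1L) > 10L * k)
          stop("contradictory spec: passive rate exceeds capacity")
        i <- if (length(ok) == 1L) ok else sample(ok, 1L)
        slots[i] <- "regulated"; slots[i + 1L] <- "by"
        plain[i] <- plain[i + 1L] <- FALSE
        placed <- placed + 1L
      }
    } else {
      avail <- which(plain)
      if (length(avail) < k)
        stop("contradictory spec: feature rate exceeds capacity")
      idx <- if (length(avail) == 1L) avail else sample(avail, k)
      slots[idx] <- sample(feature_words[[f]], k, replace = TRUE)
      plain[idx] <- FALSE
    }
  }
  # entity mentions: single-token replacements, recorded for gold offsets
  mention_slot <- integer(0); mention_text <- character(0)
  mention_class <- character(0)
  for (cl in names(p$mention_rates)) {
    k <- stats::rpois(1L, p$mention_rates[[cl]] * total1 / 1000)
    if (k == 0L) next
    avail <- which(plain)
    if (length(avail) < k)
      stop("contradictory spec: mention rate exceeds capacity")
    idx <- if (length(avail) == 1L) avail else sample(avail, k)
    forms <- sample(MENTION_SURFACE_FORMS[[cl]], k, replace = TRUE)
    slots[idx] <- forms
    plain[idx] <- FALSE
    mention_slot <- c(mention_slot, idx)
    mention_text <- c(mention_text, forms)
    mention_class <- c(mention_class, rep(cl, k))
  }
  # sentence surface: capitalize initial tokens, terminate final tokens
  slots[is_initial] <- paste0(toupper(substr(slots[is_initial], 1L, 1L)),
                              substring(slots[is_initial], 2L))
  slots[is_final] <- paste0(slots[is_final], ".")
  starts0 <- cumsum(c(0L, nchar(slots) + 1L))[seq_along(slots)]
  list(text = paste(slots, collapse = " "),
       token_total = total1,
       sentence_lengths = as.integer(
         tapply(nchar(slots) - nchar(gsub("[[:space:]]+", "", slots)) + 1L,
                sent_id, sum)),
       paren_counts = paren_counts,
       feature_counts = feature_counts,
       mentions = data.frame(start = starts0[mention_slot],
                             end = starts0[mention_slot] +
                               nchar(mention_text),
                             text = mention_text, class = mention_class,
                             stringsAsFactors = FALSE))
}

#' Generate a synthetic two-genre corpus
#'
#' Builds `n_docs` sectioned documents (one abstract section, one results
#' section) from a template vocabulary, planting parentheticals of each
#' category, surface-feature words, and entity mentions at the spec's
#' per-thousand rates. Every planted instance is tallied in the returned
#' manifest, and every planted mention is recorded with character offsets
#' into its genre text, giving the whole pipeline known ground truth. All
#' randomness flows from `spec$seed`; the same spec yields byte-identical
#' output.
#'
#' @param spec A [genre_spec()].
#' @return List of class `synthetic_corpus`: `documents` (list of
#'   [sectioned_document]s), `genre_texts` (list `abstract`/`body` of named
#'   character vectors), `mentions` (gold `mention_set`), `token_totals`,
#'   `sentence_lengths`, and `manifest` (planted rates and per-genre planted
#'   counts).
#' @export
generate_corpus <- function(spec = genre_spec()) {
  stopifnot(inherits(spec, "genre_spec"))
  set.seed(spec$seed)
  genres <- c("abstract", "body")
  texts <- list(abstract = character(0), body = character(0))
  slens <- list(abstract = integer(0), body = integer(0))
  token_totals <- c(abstract = 0L, body = 0L)
  paren_tot <- list(); feat_tot <- list()
  for (g in genres) {
    paren_tot[[g]] <- stats::setNames(integer(length(PAREN_CATEGORIES)),
                                      PAREN_CATEGORIES)
    feat_tot[[g]] <- stats::setNames(numeric(4),
                                     names(spec[[g]]$feature_rates))
  }
  docs <- vector("list", spec$n_docs)
  men <- list()
  for (d in seq_len(spec$n_docs)) {
    doc_id <- sprintf("doc%03d", d)
    parts <- list()
    for (g in genres) {
      gd <- generate_genre_doc(spec[[g]])
      parts[[g]] <- gd
      texts[[g]][doc_id] <- gd$text
      slens[[g]] <- c(slens[[g]], gd$sentence_lengths)
      token_totals[[g]] <- token_totals[[g]] + gd$token_total
      paren_tot[[g]] <- paren_tot[[g]] + gd$paren_counts
      feat_tot[[g]] <- feat_tot[[g]] + gd$feature_counts
      if (nrow(gd$mentions) > 0L)
        men[[length(men) + 1L]] <- cbind(
          data.frame(doc_id = doc_id, genre = g, stringsAsFactors = FALSE),
          gd$mentions)
    }
    docs[[d]] <- sectioned_document(
      doc_id, kinds = c("abstract", "results"),
      texts = c(parts$abstract$text, parts$body$text))
  }
  men <- if (length(men)) do.call(rbind, men) else
    data.frame(doc_id = character(0), genre = character(0),
               start = integer(0), end = integer(0), text = character(0),
               class = character(0), stringsAsFactors = FALSE)
  mentions <- mention_set(men$doc_id, men$genre, men$start, men$end,
                          men$text, men$class)
  manifest <- list(
    seed = spec$seed, n_docs = spec$n_docs,
    rates = list(abstract = spec$abstract, body = spec$body),
    token_totals = token_totals,
    planted_parens = paren_tot,
    planted_features = feat_tot,
    planted_mentions = lapply(c(abstract = "abstract", body = "body"),
                              function(g) table(men$class[men$genre == g])))
  structure(list(documents = docs, genre_texts = texts,
                 mentions = mentions, token_totals = token_totals,
                 sentence_lengths = slens, manifest = manifest),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d docs, %d abstract tokens, %d body tokens, %d gold mentions\n",
              length(x$documents), x$token_totals[["abstract"]],
              x$token_totals[["body"]], nrow(x$mentions)))
  invisible(x)
}

#' Annotation corruption specification
#'
#' Simulated tagger error model: each gold span is dropped with probability
#' `miss`; surviving spans get a boundary error (offsets shifted by one
#' character, so exact matching fails) with probability `boundary`;
#' spurious spans are inserted at `false_alarm_per_thousand` per thousand
#' tokens of non-mention text.
#'
#' @param miss Miss rate in \[0, 1\].
#' @param false_alarm_per_thousand Non-negative insertion rate.
#' @param boundary Boundary-error rate in \[0, 1\].
#' @param seed Integer seed.
#' @return List of class `corruption_spec`.
#' @export
corruption_spec <- function(miss = 0, false_alarm_per_thousand = 0,
                            boundary = 0, seed = 1L) {
  stopifnot(miss >= 0, miss <= 1, boundary >= 0, boundary <= 1,
            false_alarm_per_thousand >= 0)
  structure(list(miss = miss,
                 false_alarm_per_thousand = false_alarm_per_thousand,
                 boundary = boundary, seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Corrupt gold annotations into simulated tagger output
#'
#' @param gold Gold `mention_set`.
#' @param spec A [corruption_spec()].
#' @param corpus The `synthetic_corpus` the gold set came from; required
#'   when `false_alarm_per_thousand > 0` (spurious spans need token
#'   positions to land on).
#' @return Predicted `mention_set`.
#' @export
corrupt_annotations <- function(gold, spec, corpus = NULL) {
  stopifnot(inherits(spec, "corruption_spec"))
  set.seed(spec$seed)
  keep <- stats::runif(nrow(gold)) >= spec$miss
  pred <- gold[keep, , drop = FALSE]
  if (nrow(pred) > 0L && spec$boundary > 0) {
    shift <- stats::runif(nrow(pred)) < spec$boundary
    pred$start[shift] <- pred$start[shift] + 1L
    pred$end[shift] <- pred$end[shift] + 1L
  }
  if (spec$false_alarm_per_thousand > 0) {
    if (is.null(corpus))
      stop("false-alarm insertion requires the source corpus")
    extra <- list()
    for (g in names(corpus$genre_texts)) {
      for (doc_id in names(corpus$genre_texts[[g]])) {
        text <- corpus$genre_texts[[g]][[doc_id]]
        tk <- token_cores(text)
        n_fa <- stats::rpois(1L, spec$false_alarm_per_thousand *
                               nrow(tk) / 1000)
        if (n_fa == 0L) next
        gold_here <- gold[gold$doc_id == doc_id & gold$genre == g, ,
                          drop = FALSE]
        free <- which(!(tk$start - 1L) %in% gold_here$start)
        if (length(free) == 0L) next
        idx <- free[sample.int(length(free), min(n_fa, length(free)))]
        extra[[length(extra) + 1L]] <- data.frame(
          doc_id = doc_id, genre = g, start = tk$start[idx] - 1L,
          end = tk$end[idx], class = "gene", text = tk$core[idx],
          stringsAsFactors = FALSE)
      }
    }
    if (length(extra))
      pred <- rbind(pred, do.call(rbind, extra))
  }
  pred <- pred[order(pred$doc_id, pred$genre, pred$start), , drop = FALSE]
  rownames(pred) <- NULL
  mention_set(pred$doc_id, pred$genre, pred$start, pred$end, pred$text,
              pred$class)
}
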