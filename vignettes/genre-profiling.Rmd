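---
title: "Profiling abstracts against article bodies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling abstracts against article bodies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genreprof)
```

## The measurement problem

A scientific article contains two text populations with different
communicative jobs: the abstract, written to summarize for skimming
readers, and the body, written to document methods and evidence. Language
processing tools tuned on one population can degrade on the other, so the
differences need to be measured, not assumed. `genreprof` operationalizes
that comparison as a fixed battery of surface measurements — each cheap,
deterministic, and deliberately simple enough to audit — plus the
statistical machinery to decide which differences are real.

The genre partition itself is configurable, because two conventions are in
use: the abstract genre may or may not include the title, and the body may
or may not include the bibliography. `partition_genres()` exposes both
flags. Defaults: title included, bibliography excluded — except for
sentence-length statistics, which always drop the title, because titles
are not sentences and would distort length distributions. When both
variants of an analysis are meaningful, run both; the flags are per-call.

## Units and normalization

Every density in the package is per thousand whitespace tokens:
`density_per_thousand(count, W) = 1000·count/W`. Whitespace tokenization
(maximal runs of non-whitespace) is the corpus-linguistics convention for
word counting; it makes `W` reproducible by anyone with the text and no
tokenizer of their own. Word-set counters strip edge punctuation from
tokens before matching (so `"And,"` counts as a coordinator), but the
token total `W` is always the raw whitespace count. Density on empty text
is an error, never zero or `NaN`.

## The measurement battery

**Sentence segmentation** is a rule cascade: a boundary requires terminal
punctuation, a following capital or digit after whitespace, a preceding
word that is not in a biomedical abbreviation stoplist (`et al.`, `Fig.`,
`e.g.`, ...) or a bare initial, and parenthesis depth zero — no boundary is
ever placed inside a balanced `( )` pair. The original study used a
trained Medline sentence model; this package does not reimplement it,
because every downstream statistic consumes only sentence counts and
lengths, not model-specific boundaries. The segmenter is therefore a
pluggable argument: any `function(text)` returning the same span frame can
be swapped in.

**Parenthesized spans** are extracted as outermost balanced pairs (nested
pairs stay inside their parent's content; lone parentheses are tallied,
not matched) and classified by a precedence cascade: citation →
figure/table pointer → P-value → list enumerator → singular/plural →
part-of-gene-name → data value → abbreviation/symbol → parenthetical
statement → unknown. Most-specific first; P-values outrank data values
because a P-value is a data string with extra structure. The regex
component lives in a versioned plain-text file
(`inst/extdata/paren_patterns.tsv`) so the patterns are auditable and
replaceable; structural rules — whether the `(` is glued to the preceding
word (as in `gene(s)` and `NF-kappa(b)`), token counts, left context —
are applied in code. Two boundary decisions worth knowing: an
abbreviation/symbol needs ≤3 alphanumeric tokens carrying a capital or
digit plus a non-empty left context, while a parenthetical statement needs
≥3 tokens including a lowercase function word — that is what separates
`(QTLs)` from `(LRS of 17.5 near D10Mit186)`. Spans whose
comma/semicolon-separated pieces match more than one regex category are
classified deterministically by the cascade but flagged `mixed` for
diagnostics.

**Surface features** follow published surface patterns exactly, with their
acknowledged error modes: the passive cue is a token ending in `-ed`
followed by `by` (default), which misses agentless and conjoined passives
and matches `the bed by the wall`; a literal-substring mode (`"ed by"`
anywhere) is provided for bit-for-bit fidelity to the original procedure.
Under- and over-counting apply equally to both genres, which is what keeps
the comparison valid. The pronoun inventory defaults to the third-person
neuter/plural forms (`it, its, itself, they, them, their, themselves`) and
is an explicit argument — nonreferential *it* is deliberately not
excluded.

**Complexity.** The syntactic complexity index weights subordinating
conjunctions and WH-words at 2 and verb forms and noun phrases at 1. Noun
*phrase* counting requires a parser, which this package does not ship; the
bundled labeler (`label_lexical_classes()`) counts noun *tokens* instead
and marks the output with a `noun_proxy` attribute. Any labeler producing
the same two-column frame can replace it. The function-word list for the
readability percentage is a fixed ~230-entry file shipped with the
package; the metric is only comparable across texts scored with the same
list, which is why the list is a visible input rather than a hidden
constant.

**Kullback–Leibler comparison.** Score distributions are binned on equal
width edges over a shared range (default 20 bins); `KL(p,q) = Σ pᵢ
log(pᵢ/qᵢ)` in natural log by default. `q` is smoothed by `ε = 1e-9` and
renormalized *only when* it has empty bins that `p` occupies, so
`KL(p,p)` is exactly 0 while every divergence stays finite; `0·log 0`
terms contribute 0. Bin edges must match exactly or the comparison errors
— silently rebinning two samples differently is the classic way to
fabricate divergence.

**Dictionary matching** is case-insensitive longest-match over whole
words: match boundaries must coincide with token boundaries after edge
punctuation stripping, multi-word entries match across single spaces, and
overlaps resolve longest-first, left-to-right, independent of dictionary
order. The four filtering rules (drop names with `()[]+.` characters,
amino-acid names, general-English words, names under five characters) are
applied in that order with per-rule removal tallies. The English wordlist
is a compact curated frequency list shipped as text; substitute any larger
list — it is an input, not a constant.

**Span scoring** is exact-boundary matching only: a prediction is a true
positive iff a gold span with identical document, genre and offsets
exists. Overlapping spans within one annotation set are rejected rather
than silently resolved. `prf()` accepts an explicit `gold_total` recall
denominator for the situation where the annotation total is known
independently and disagrees slightly with `TP+FN` in a published
confusion table; precision/recall/F are kept unrounded until printing.

**Bracket recall** is the compatibility-based variant: candidate
constituents that cross no gold constituent boundary, divided by the
number of gold constituents, with single-word constituents excluded from
both counts. This differs from standard labeled PARSEVAL recall — labels
are ignored, and a candidate with more non-crossing brackets than the
gold tree has constituents can score above 1. The value is returned
uncapped and the divergence documented here and in the function help.

## Significance testing

`compare_samples()` encodes the test-selection policy: Shapiro–Wilk at α
= .05 on both samples (the gate test is this package's choice; zero
variance fails, n > 5000 is gated on a deterministic evenly-spaced
subsample because Shapiro–Wilk is defined up to 5000); if both pass, a
Welch two-sample two-tailed t-test; otherwise a two-sided Mann–Whitney U
(exact for small tie-free samples, normal approximation with tie
correction otherwise). The name "Mann–Whitney–Wilcoxon signed-rank" in
the corpus-linguistics literature conflates two tests; for two independent
genre samples the U test is the coherent reading and is the default, but a
paired Wilcoxon signed-rank variant is available for per-document paired
designs. Multiple comparisons use Bonferroni, `min(1, p·m)` — over the
four surface features `m = 4`, over pairwise comparisons of `k` sections
`m = C(k,2)` (21 for seven sections). Densities are compared at the
document level — one density value per document per genre — because the
tests need samples, not single aggregates.

## The synthetic corpus: what it does and does not show

`genre_spec()` pins the generator's defaults to the study conditions of a
97-article mouse-genomics full-text corpus: lognormal sentence lengths
(meanlog 3.197/3.341, sdlog 0.35 → means ≈26/≈30 words; right-skewed, so
the lengths correctly fail the normality gate), parenthesis incidence
10/28 per thousand with the genre-specific category mixtures, feature
rates 36.2/37.5 (coordination), 3.7/4.3 (passives), 3.8/5.3 (negation),
5.3/3.98 (pronouns), and mention densities 61/47 (genes), 0.08/0.28
(mutations), 2.97/2.21 (drugs), 4.1/3.74 (diseases).

Generation works by replacement in a filler vocabulary chosen to be inert
— no filler word is a coordinator, negator, pronoun, `by`, an `-ed` form,
or a planted entity name — so planted counts equal measured counts
exactly, and the only randomness is the Poisson/multinomial planting
itself. Parentheticals are inserted as exemplar-shaped templates (one per
category) with the instance count drawn against the post-insertion token
total, so measured incidence is unbiased despite insertions growing the
text. All randomness flows from the single spec seed; the same spec is
byte-identical across runs. Gold mentions are recorded with character
offsets into each document's genre text, and `corrupt_annotations()`
turns them into simulated tagger output with independent miss, boundary
(one-character offset shift) and false-alarm processes.

What passing tests on this corpus demonstrate: the counters count, the
classifier classifies, the matcher matches, offsets are exact, the
statistics detect planted differences of the published magnitudes and stay
quiet under the null. What they do not demonstrate: performance on real
prose. The generator's sentences are not grammatical English; its
parentheticals are single fixed shapes per category, so classifier
accuracy on it is 100% by construction, unlike the ~76–100% per-category
accuracy real text yields; its mentions are single tokens. Real-corpus
absolute values (medians of real sentence lengths, absolute tagger
scores) are outside what any synthetic corpus can certify.

## Numerical and design choices

* Character offsets are 0-based and half-open everywhere (sections,
  sentences, parentheticals, mentions) — one convention across all
  scorers.
* Medians use the midpoint-of-two rule; length statistics are
  recomputable from the stored lengths.
* Problem sizes used by the shipped test suite and acceptance script:
  end-to-end recovery runs on a ≈110k-token body genre (16 documents of
  205 sentences); genre-difference detection uses 1000 documents per
  genre of 8 sentences each; null calibration uses 1000 replicates of
  n = 40 Poisson samples with the analysis-scale Bonferroni factor m = 4.
  These sizes give 3σ Poisson/binomial bounds that are tight relative to
  the planted rates while keeping the suite fast.
* Recovery tests use 3σ bounds computed from the planted rate itself
  (`3·sqrt(rate·1000/W)` for a density over `W` words), with a 3-count
  floor for the rarest categories where the normal approximation is poor.
* `run_full_analysis()` skips stages whose inputs are missing (with a log
  entry) instead of aborting, and persists every table as TSV next to a
  markdown digest so each reported number is recomputable from the
  written intermediates.

## Known limitations

The sentence splitter is a heuristic cascade, not a trained model;
its abbreviation stoplist is finite. The parenthetical cascade is
re-derived from category definitions and exemplars, not from the original
(unpublished) patterns, so per-category accuracy on real text should be
re-validated before substantive use. The noun-token proxy inflates the
complexity index on noun-compound-heavy prose. The general-English filter
list is deliberately small; a production drug matcher should supply a
10k-word frequency list. Only exact span matching is implemented —
alternative-boundary protocols used by some shared tasks are out of
scope.
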