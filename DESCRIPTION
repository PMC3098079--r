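Package: genreprof
Title: Genre Profiling of Biomedical Article Abstracts and Bodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures structural and content differences between the two
    genres of a scientific article: its abstract (optionally with title)
    and its body (optionally without bibliography). Provides readers for a
    minimal PMC-style XML dialect and a sectioned plain-text dialect,
    rule-based sentence segmentation and whitespace tokenization,
    extraction and classification of parenthesized text into nine
    categories, per-thousand-token densities of coordination, negation,
    passive and pronoun cues, sentence-complexity and readability metrics
    with Kullback-Leibler comparison, dictionary-based drug-name matching
    with auditable filtering rules, entity-mention density reports,
    span-level precision/recall/F and PARSEVAL-style bracket recall and
    tag accuracy, a normality-gated significance-testing procedure with
    Bonferroni correction, and a synthetic two-genre corpus generator with
    planted ground truth so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
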