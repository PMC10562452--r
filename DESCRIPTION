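Package: gestprot
Title: Cross-Species Gestational-Age Analysis of Multi-Plex Isobaric-Label Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for longitudinally sampled amniotic-fluid
    proteomes quantified by multi-plex isobaric labeling. Harmonizes reporter-ion
    intensities across plexes with internal reference scaling (IRS), normalizes
    samples with trimmed-mean-of-M-values factors plus library scaling and log
    transformation, fits per-protein linear models of log2 abundance on
    gestational age (days) with empirical-Bayes variance moderation and optional
    within-subject blocking, joins two species on 1:1 orthologs to quantify
    abundance and effect-size concordance, performs hypergeometric
    over-representation and tissue-signature enrichment, and summarizes
    longitudinal tissue trajectories as reference-anchored Z-scores. Ships a
    synthetic-data generator with known ground truth so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    edgeR,
    ggplot2
Config/testthat/edition: 3
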