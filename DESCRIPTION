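Package: rhizoclass
Title: Comparative Rhizosphere Transcriptomics: Two-Color Arrays,
    Specificity Classification, Colonization Index and qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for comparative rhizosphere transcriptomics of
    Rhizobium leguminosarum: processing of two-color microarray spot
    tables (background subtraction, robust loess normalization,
    replicate-level log-ratio statistics), multi-rhizosphere
    differential-expression and specificity classification under
    fold-change/P-value threshold rules, replicon-enrichment and Venn
    summaries, the Rhizosphere Colonization Index (RCI) from competition
    CFU counts, and comparative-CT (delta-delta-CT) qPCR confirmation
    with a permutation ratio test. Includes a synthetic-data generator
    that plants specificity categories, intensity-dependent dye bias,
    strain fitness and expression ratios as recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
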