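Package: dmrescue
Title: Individual-Level Transcriptomic Rescue Analysis for Myotonic Dystrophy Training Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how far an exercise intervention shifts a myotonic
    dystrophy type 1 (DM1) patient's transcriptome back toward unaffected
    controls, one individual at a time. Implements percent-rescue scoring and
    classification (rescued / overrescued / misrescued) for skipped-exon PSI
    and gene-expression log2 fold changes, splicing and gene-expression
    dysregulation scores, shared-rescue set intersections (upset semantics),
    YGCY (MBNL-binding) motif enrichment against composition-matched
    backgrounds, clinical meaningful-change assessment (SEMT / minimal
    detectable change), and Spearman / age-controlled partial Spearman
    correlation of molecular rescue with clinical strength gains. A synthetic
    cohort generator with full ground truth makes the whole pipeline testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
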