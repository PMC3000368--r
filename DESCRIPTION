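Package: prc2scan
Title: GC-Rich Element Discovery and Polycomb ChIP Analysis
Version: 0.1.0
Authors@R: person("prc2scan", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A windowed-sequence and ChIP analysis toolkit for studying the
    recruitment of Polycomb repressive complex 2 (PRC2) to GC-rich DNA
    elements. Provides sliding-window GC content and CpG observed/expected
    scans, CpG-island calling, discovery of GC-rich candidate elements
    depleted of activating transcription-factor motifs in arbitrary genomes,
    position-weight-matrix motif scanning with an exact score-distribution
    p-value, windowed ChIP-Seq enrichment calling against an empirical
    randomized-read null, promoter chromatin-state (bivalency) and CpG-class
    classification, RNA-Seq exonic activity scoring, bisulfite methylation
    composites, ChIP-qPCR fold-enrichment quantification, and seeded
    synthetic-data generators with ground-truth records for closed-loop
    testing of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
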