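Package: pssScreen
Title: Transposase Signal Sequence Detection at Structural Variant
    Breakpoints in Forward Genetic Screens
Version: 0.1.0
Authors@R:
    person("pssScreen", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for amplicon-based forward genetic screens
    that read out rearrangements of a single selectable locus (the HPRT1
    thioguanine assay). Detects transposase signal sequences (PSS) at
    structural-variant breakpoints by inverted-orientation flank alignment,
    filters short repeats and control-cohort matches, summarises motifs as
    breakpoint-anchored position frequency matrices with per-column
    information content, classifies inactivating rearrangements, and
    provides the screen statistics: mutational frequency, clonogenic
    efficiency, the exact Poisson rate-ratio test with Clopper-Pearson
    intervals, the exact two-sided binomial test, and 40-bp windowed
    variant profiles. Includes a synthetic locus/cohort generator with
    planted inverted-terminal-repeat elements for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
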