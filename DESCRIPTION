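Package: enhancerkit
Title: Super-Enhancer Calling, Motif Enrichment and Target-Gene Assignment
    for Transcription-Factor Regulomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Regulatory-genomics toolkit around a stimulated transcription
    factor and its chromatin context. Identifies typical and super enhancers
    from H3K27ac peaks by distal filtering against gene TSS, 12.5 kb
    stitching, total-signal ranking and a slope-1 tangent cutoff on the
    unit-scaled signal curve; predicts transcriptional co-regulators from
    fixed-width peak-summit flank sequences by average-odds position weight
    matrix scoring and one-sided Wilcoxon rank-sum enrichment of a condition
    set against a control set; assigns peaks to nearest-TSS genes, calls
    target genes as bound-and-differentially-expressed, classifies co-binding
    between two peak sets by a summit-distance rule, and computes average
    signal profiles around genomic anchors. A seeded synthetic-data generator
    plants super enhancers, motif instances and differentially expressed
    genes with a machine-readable ground truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
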