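Package: cnvsieve
Title: Copy-Number Variant Calling and Rare-Variant Filtering for SNP-Array Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A case-control pipeline for discovering ultra-rare copy-number
    variants (CNVs) from SNP-array intensity signals. Provides a seedable
    simulator of per-probe LogR-ratio and B-allele-frequency data with planted
    deletions and duplications, a five-state hidden Markov model segmenter run
    under three caller-like parameter profiles, log Bayes factor call scoring,
    a filter cascade (sample QC, call QC, control-cohort containment exclusion,
    three-caller consensus intersection, size and frequency-database filters)
    with full per-call provenance, gene/promoter content annotation with
    biotype summaries, and evidence-based candidate prioritization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomeInfoDb,
    BiocGenerics,
    jsonlite,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
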