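Package: ecfmap
Title: Mapping Extracytoplasmic-Function Sigma-Factor Regulons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the regulon of an extracytoplasmic-function (ECF) sigma
    factor from ChIP enrichment data, as applied to the sigma-E cell-envelope
    stress regulon of Streptomyces coelicolor. Provides windowed enrichment
    peak calling against an input control, a two-block Gibbs sampler for
    gapped promoter motifs (-35 tetramer, 16-17 bp spacer, -10 pentamer),
    position weight matrix construction from validated promoters and upstream
    window scanning, classification of targets by promoter dependence from
    wild-type versus deletion-mutant induction time courses, and cross-genome
    conservation of target promoters via reciprocal-best-hit orthologs.
    Seeded synthetic-data generators emulate every input so the full pipeline
    can be exercised and benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    BiocGenerics,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
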