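Package: emmerSurvey
Title: Downstream Analysis of Chromosome-Based Survey Sequencing for a
    Tetraploid Wheat Genome
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for the downstream computational
    analysis of chromosome-based survey sequencing of an allotetraploid
    (AABB) wheat genome: reference-guided super-scaffolding with an N-gap
    merge rule and assembly statistics, repeat-landscape summarisation from
    a library masker, best-reciprocal-hit orthology with Markov clustering
    and conserved gene-content estimation, homology-based miRNA hairpin
    annotation with transposable-element-overlap confidence classes, a long
    noncoding RNA elimination cascade with a per-transcript audit trail,
    SSR and ISBP (transposable-element junction) marker discovery, variant
    summarisation, and link-based synteny bundling with translocation
    detection. A synthetic tetraploid genome generator with a ground-truth
    manifest makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    Matrix,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Annotation, SequenceMatching, Alignment
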