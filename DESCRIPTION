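Package: polyChIP
Title: Reproducibility-Tiered ChIP-seq Peak Filtering and Direct-Target
    Classification in Polyploid Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative classification of transcription-factor direct and
    indirect target genes in allopolyploid genomes from replicate ChIP-seq
    peak sets and RNAi differential-expression tables. Provides tiered
    reproducibility filtering of replicate peaks (fold-enrichment and q-value
    thresholds, summit-distance matching, a rank-based Gaussian copula
    mixture estimator of the irreproducible discovery rate, nested validation
    levels), strand-aware promoter-window target assignment and TSS-relative
    peak annotation, subgenome binding-bias chi-square tests against
    chromosome-size-proportional expectations, hypergeometric functional-bin
    enrichment, proximity-labeling candidate filtering, and a synthetic-data
    generator that emulates a four-subgenome by seven-chromosome-group
    genome with planted signal so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
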