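Package: alleleMeth
Title: Allele-Resolved DNA Methylation and Expression Analysis for Hybrid Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing DNA methylation and gene expression at allele
    resolution in hybrid (two-subgenome) plant genomes, motivated by de novo
    shoot organogenesis time courses. Implements weighted methylation levels and
    80-bin metagene profiles from bisulfite cytosine reports, sliding-window
    differential-methylation-region (DMR) calling with replicate-aware
    binomial-logistic likelihood-ratio tests, time-course profile clustering,
    TPM quantification and negative-binomial GLM tests for differential and
    allele-specific expression (including phase-dependent interaction tests),
    subgenome allele pairing by synteny chaining, bidirectional best hits and
    single-copy orthology, allele-specific methylation region (ASMR) calling,
    and promoter transcription-factor-binding-site scanning with exact PWM
    p-values and cosine-similarity comparison of allele promoters. A synthetic
    diploid-hybrid data generator with complete ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
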