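Package: kbcascade
Title: Classifying NF-kB Target Genes from Kinetic Expression, Binding, and
    Chromatin Looping Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for classifying transcription-factor
    target genes from time-course RNA-seq, replicate ChIP-seq peak sets,
    perturbation experiments (inducible dominant-negative IkBa), RNA
    polymerase II ChIA-PET interaction data, and cross-species kB-motif
    conservation. Provides reproducible-peak filtering and peak-to-gene
    assignment, RPM normalization and a pluggable differential test,
    correlation-distance k-means with silhouette and elbow diagnostics, a
    direct/indirect activated/repressed target taxonomy, PET-cluster
    filtering and promoter-loop categorization, PWM promoter scanning with
    ortholog conservation scoring, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
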