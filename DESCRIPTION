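Package: methtrace
Title: Historic CpG Methylation Footprints in Transcript and Genomic Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers historic germline DNA methylation from sequence composition.
    Computes per-gene dinucleotide observed/expected ratios with an N-aware
    correction, tests CpG O/E distributions for departure from unimodality with
    a two-component Gaussian mixture EM fit and a parametric bootstrap
    likelihood-ratio test, classifies genes into historically methylated (low
    CpG O/E) and unmethylated (high CpG O/E) populations, performs EASE-style
    (jackknifed one-sided Fisher) GO term enrichment with Benjamini-Hochberg
    correction, and emulates methylation-sensitive HpaII/MspI restriction
    digests in silico. A CpG-deamination sequence-evolution simulator generates
    unigene sets, annotation tables and repeat-bearing genomes with known
    ground truth for validating the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
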