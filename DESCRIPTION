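Package: parastx
Title: Mixed-Species Transcriptome Deconvolution and Host-Parasite
    Interface Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for separating host and parasite transcripts in
    mixed-species RNA-seq of the haustorial interface between a parasitic
    plant and its hosts, and for comparative analysis of the resulting
    interface transcriptomes. Provides quality trimming of paired-end
    reads with pair/orphan accounting, a self-contained k-mer seeded
    banded nucleotide aligner for identity screening and read mapping,
    calibration of the host-exclusion percent-identity threshold from
    best-hit identity distributions, a staged unigene classification
    cascade with full count accounting, orthogroup Venn partitioning with
    GO Slim proportionality tests (Pearson chi-square with residual
    flags), RPKM quantification and expression ranking, relative qPCR
    quantification by the 2^-ddCt method with Welch one-tailed tests, and
    a seeded synthetic-data generator with ground truth so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
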