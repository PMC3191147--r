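Package: mmsdk
Title: Genome-Wide DNA Methylation Profiling from Methylation-Sensitive
    Restriction Tag Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the computational pipeline for modified
    methylation-specific digital karyotyping (MMSDK) experiments, in which
    the methylation-sensitive enzyme MluI cuts only unmethylated ACGCGT
    sites and 17-bp sequence tags released next to flanking NlaIII (CATG)
    sites are sequenced. The package performs in-silico MluI/NlaIII
    digestion of a genome to build a virtual tag library with uniqueness,
    CpG-island, repeat and gene annotation; maps observed 17-bp tags at two
    confidence tiers analogous to MAQ's MQ20/MQ0; builds per-site count
    matrices; applies mean/standard-deviation tag filtering and
    library-total normalization; clusters libraries with Pearson
    correlation distance and multiscale-bootstrap AU/BP support values;
    and calls differentially methylated loci with an exact Poisson-rate
    test followed by Benjamini-Hochberg adjustment, with Wilcoxon
    rank-sum tests for repeat classes and Fisher's exact test for
    bisulfite validation counts. A synthetic-data module generates
    genomes, methylomes and tag reads with known truth so that every
    stage of the pipeline can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
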