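Package: genopack
Title: Versioned Gene-Anchored Data Packages for Microbial Genomes and Pangenomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, version and query self-contained data packages anchored on a
    microbial genome or pangenome. A package carries the genome sequence, gene
    calls and multi-source functional annotations as its spine, and accumulates
    checksummed, gene-referenced data layers (per-sample transcript coverage,
    proteome spectral counts, arbitrary per-gene data, named gene collections)
    under semantic versioning with a changelog. Analysis operations cover TPM
    and NSAF normalization, proportional expression over gene collections with
    Ward clustering and group t-tests, pangenome construction by minbit-filtered
    protein similarity and Markov clustering, fragment-based average nucleotide
    identity, completeness-aware Bayesian core/accessory classification, CAZyme
    category profiling, concatenated single-copy-core alignments, newick
    midpoint rooting and Robinson-Foulds topology comparison. Deterministic
    synthetic-data generators make the whole toolkit testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
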