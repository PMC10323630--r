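Package: polyphase
Title: Subgenome Phasing and Progenitor Assignment for Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for resolving the subgenome structure of allopolyploid
    genome assemblies: differential k-mer identification and hierarchical
    clustering of chromosomes into subgenomes, repeat-density profiling and
    centromere estimation, read-depth binning and subgenome dosage inference,
    collinear anchor chaining and syntelog-based progenitor assignment from
    bootstrap-supported gene-tree sister relationships, gene-tree topology
    censuses, penalized-likelihood divergence dating, Nei-Gojobori Ka/Ks
    estimation with Ks-peak diagnosis of allopolyploidy, and rule-based
    annotation and marker quality control. Includes a synthetic
    allotetraploid genome generator with planted subgenome structure so the
    whole pipeline can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    mclust,
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
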