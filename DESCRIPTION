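Package: isopick
Title: Isoform Selection for Phylogenetic Datasets by Alignment-Perturbation Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects one protein isoform per genomic locus before phylogenetic
    reconstruction. Sequences are scored by a Sum-of-Pairs agreement between a
    reference multiple alignment and a set of perturbed alignments, each built
    with a guide tree inferred (BioNJ) from a bootstrap resample of the
    reference alignment's columns. Scoring variants penalize gap-inducing
    isoforms, short isoforms, or replace the bootstrap by a modified p-distance
    score for large datasets, with an automatic variant chooser. Includes
    pairwise protein distances under Poisson, PAM/Kimura, JTT, WAG, LG and
    BLOSUM62-derived models, a deterministic built-in progressive aligner,
    adapters for external aligners, and a synthetic gene-family simulator with
    known canonical isoforms for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    graphics,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
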