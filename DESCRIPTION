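Package: minorhap
Title: Detection and Phasing of Minor Single-Nucleotide Variants from
    Noisy Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects single-nucleotide variants present in a small
    fraction (down to roughly one percent) of a mixed sample from
    long-read alignments whose per-base error rate is far higher than
    the variant frequency, and phases the detected variants into
    haplotype contigs. Reads are encoded as sets of substitution codes;
    minor SNVs are detected through maximal conditional substitution
    rates estimated by a greedy search restricted to read-pair
    subspaces (random subspace maximization), complemented by a
    homopolymer-context gradient-boosting error model with a
    likelihood-ratio test for orphan SNVs. Detected variants are
    refined by local Smith-Waterman realignment against base-modified
    references, phased by adaptive-nearest-neighbour read clustering,
    screened with Bayes factors, and assembled into contigs on a
    transitively reduced overlap graph. A seeded simulator generates
    references, haplotype mixtures and noisy reads so that every stage
    is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    Rsamtools,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
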