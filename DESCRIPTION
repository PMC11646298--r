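Package: mitobench
Title: Accuracy Benchmarking of Long-Read Mitochondrial Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Circular-aware comparison of a long-read assembled mitochondrial
    genome against a short-read ('gold standard') reference. Normalizes the
    rotation and strand of a circular query, performs end-to-end global
    alignment with affine gap penalties, computes p-distance and completeness,
    and classifies every discrepancy into a nanopore-oriented error taxonomy
    (homopolymer insertions/deletions by multiplicity, simple substitutions,
    single and short indels, tandem duplications). Also provides read
    filtering by mean quality and length, seeded subsampling to a target
    sequencing depth, descriptive mitogenome statistics (nucleotide usage,
    codon usage and RSCU, microsatellite and tandem-repeat scans, annotation
    summaries), and a fully seeded synthetic-data generator (circular A+T-rich
    genomes with planted homopolymers and control-region repeats,
    error-injected assembly copies with exact per-category truth, ONT-like
    simulated reads) so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
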