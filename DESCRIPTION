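Package: pmoaclass
Title: Taxonomic Classification and Novelty Detection for pmoA Amplicon
    Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying high-throughput amplicon reads of pmoA,
    the beta-subunit gene of particulate methane monooxygenase, against a
    curated hierarchical taxonomy of copper-containing membrane-bound
    monooxygenase (CuMMO) sequences. Provides the packaged 54-taxon pmoA
    taxonomy with importers and exporters (tabular, Newick plus map file,
    mothur-style taxonomy files, BLAST-style reference FASTA); amplicon
    quality filtering; a naive Bayesian k-mer classifier with bootstrap
    confidence estimates; a seed-and-extend local nucleotide aligner with
    Karlin-Altschul bit scores and a six-frame translated search mode; a
    lowest-common-ancestor (LCA) classifier over bit-score margins; a
    four-tier novelty-detection procedure including conserved-mismatch
    profiling; cross-sample count tables, subsampling and ecological
    distance matrices; and a seeded synthetic read generator with ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
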