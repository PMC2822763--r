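Package: concordtf
Title: Function-Conservation Discovery of Interacting Transcription Factor Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts interacting transcription factor (TF) pairs, tissue and
    tissue-type TF pairs, TF-TF interaction networks and conserved three-TF
    modules from paired orthologous promoter sequences of two species. The
    approach scores a TF pair by the coupling between two ten-point profiles
    over a 20-200 bp distance-constraint grid: enrichment of co-occurring
    binding sites in real versus shuffled promoters, and enrichment of
    overlapping orthologous target genes. Includes a Match-style position
    weight matrix scanner with calibrated thresholds, mononucleotide and
    dinucleotide-preserving promoter shuffles, permutation significance with
    Benjamini-Hochberg control, housekeeping subtraction, tissue clustering,
    network reconstruction with bootstrap enrichment of designated TF sets,
    and a synthetic two-species promoter generator with planted,
    distance-constrained, conserved binding-site pairs and triplets for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
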