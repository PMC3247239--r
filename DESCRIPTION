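Package: promoscan
Title: Motif Enrichment and Conservation Analysis for TSS-Anchored Promoter Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for rigorous discovery of enriched and evolutionarily
    conserved transcription-factor binding motifs in promoter sets of large
    gene families, modelled on the regulatory analysis of mouse olfactory
    receptor promoters. Provides MatInspector-style position-weight-matrix
    scanning at two stringencies with family-level pruning, three statistical
    tests of motif enrichment (a one-tailed binomial test against the
    preceding upstream region, an empirical null from dinucleotide-preserving
    sequence shuffles, and a one-tailed rank-sum test on per-base conservation
    scores inside versus outside predicted sites), turnover-aware
    cross-species site filtering by spanning-subtree branch length,
    consistent motif masking across real and control datasets for
    second-round discovery, TSS inference from cDNA alignments with
    recent-duplicate removal, and a fully synthetic data generator so the
    whole pipeline is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
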