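Package: lpmominer
Title: Mining and Annotation of Bacterial AA10 Lytic Polysaccharide
    Monooxygenases from Metagenomic Protein Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining putative family AA10 lytic polysaccharide
    monooxygenases (LPMOs) from metagenomic protein-coding gene sets and
    annotating them. Implements profile-HMM domain-hit filtering (score,
    profile coverage and bias/score criteria), signal-peptide removal with
    His1 mature-sequence derivation, alignment-based mapping of the
    H1-Hx-Fy active-site motif, substrate-specificity calls from the
    diagnostic residue (Ile/Val for chitin, Arg for cellulose), tryptophan
    triad and polar/gatekeeper motif detection, cysteine and disulfide
    reporting, multidomain architecture assembly with GbpA-like
    classification, neighbor-joining phylogeny with bootstrap support, and
    Kabsch superposition of C-alpha coordinate sets for structural
    detection of GbpA_3-like domains. A seeded synthetic-data generator
    produces ground-truthed cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
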