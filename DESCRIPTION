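Package: neoscape
Title: Neoantigen Immunogenicity Scoring and Clonality-Aware Tumor Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores single-amino-acid-substitution neoantigens from paired
    wild-type/mutant peptides and MHC-binding motifs using a small trainable
    cross-reactivity-distance network, and turns per-mutation scores into
    patient-level, clonality-aware tumor immunogenicity landscapes. Includes
    MHC binding-motif construction with a pluggable binding-predictor
    interface, curation of cross-reactive peptide triplets and labelled
    epitope sets, two-stage contrastive training, interpretation via affine
    transformations of residue embeddings and allele benefit scores,
    mutation-centric metrics (PHBR, robustness, agretopicity, allele
    aggregation), integrated logistic models with recursive feature
    elimination, tumor-centric landscape scores (sum, CCF-weighted,
    clone-structured), the CSiN and ioTNL benchmarks, Gini-based
    heterogeneity classification, and synthetic-data generators for all
    inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
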