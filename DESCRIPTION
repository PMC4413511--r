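Package: glysite
Title: Lysine Glycation Site Prediction from k-Spaced Amino-Acid Pair Features
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts nonenzymatic lysine glycation sites in protein
    sequences. Each candidate site is represented by a 23-residue peptide
    window (11 residues up- and downstream, 'O'-padded at sequence ends)
    encoded into a canonical 1900-dimensional feature vector: 21 residue
    occurrence frequencies, five Atchley physicochemical factors at each of
    the 23 sites, and the composition of k-spaced amino-acid pairs (CKSAAP,
    441 ordered pair types for each spacing k = 1..4). Features are ranked
    by the minimum-redundancy maximum-relevance (mRMR) mutual-information
    criterion, an optimal subset is chosen by incremental feature selection
    (IFS) with a grid-searched RBF-kernel support vector machine under
    stratified 10-fold cross-validation, and performance is reported as
    sensitivity, specificity, accuracy and the Matthews correlation
    coefficient. Includes a seeded synthetic-data generator with plantable
    pair signal, delimited-text interchange for every pipeline stage, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
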