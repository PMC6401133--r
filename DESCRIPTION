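Package: contactnet
Title: Protein Residue-Residue Contact Prediction with Fully Convolutional
    Residual Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts residue-residue contact maps of proteins from sequence
    profiles, coevolutionary couplings and mutual information using a fully
    convolutional residual neural network with a symmetrized three-class
    (contact / non-contact / ignored) output, trained by weighted
    cross-entropy and combined into an ensemble over disjoint validation
    splits. Includes native-contact extraction from PDB structures under the
    C-beta 8 Angstrom rule, CASP-style top-L/k precision evaluation,
    probability-bin precision and contact prediction depth, density-based
    (HDBSCAN) contact-pattern cluster analysis with coverage statistics,
    conversion of confident predictions into side-chain center-of-mass
    distance restraints, and a synthetic fold/alignment generator so the
    whole stack runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
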