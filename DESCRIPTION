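Package: transpred
Title: Membrane Transporter Prediction by Stacked Composition and Homology Classifiers
Version: 0.1.0
Authors@R:
    person("Transpred", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discriminates membrane transport proteins from non-transporters
    using sequence information alone. Implements psi-composition descriptors
    (amino acid, dipeptide and pseudo amino acid compositions averaged over the
    gap-free aligned regions of PSI-BLAST homologs), RBF-kernel support vector
    machine base classifiers, rule-based annotation transfer by homology
    against a transporter classification database under three threshold
    profiles, and a stacked-generalization ensemble whose gradient-boosting
    meta-classifier is trained on cross-validated base predictions. Includes
    MCC-centric evaluation via repeated stratified cross-validation and seeded
    synthetic-data generators so the full pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
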