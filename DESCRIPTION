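Package: dopasight
Title: Solvent-Accessibility-Based Prediction of Tyrosine-to-DOPA
    Modification in Adhesive Fusion Proteins
Version: 0.1.0
Authors@R:
    person("dopasight", "developers", email = "dopasight@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting tyrosinase-mediated conversion of
    surface-exposed tyrosines to L-3,4-dihydroxyphenylalanine (DOPA) in
    engineered adhesive proteins such as CsgA-MFP3 chimeras.  Implements
    a Shrake-Rupley solvent-accessible surface area (SASA) engine with a
    Monte-Carlo cross-check, relative-accessibility classification of
    tyrosines, in-structure conversion of selected tyrosines to DOPA,
    modification-dependent molecular-weight accounting, a rule-based
    catechol/quinone pH-adhesion model, and basic structure-quality
    metrics (phi/psi dihedrals, radius of gyration, RMSD).  Includes a
    deterministic generator of synthetic test structures and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
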