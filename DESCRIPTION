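Package: abgas
Title: Gas-Phase Conformational Modelling of IgG Antibodies from Ion
    Mobility Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative workflow for predicting the gas-phase
    conformations of flexible multi-domain proteins, developed around the
    four human IgG antibody subclasses. Starting from a structural model,
    the package samples Fab-arm flexibility over the upper-hinge backbone
    dihedrals with a rapidly-exploring random tree, scores conformers by
    projection-approximation collision cross section (CCS = PA x 1.14),
    selects compact conformers, simulates their charged collapse in vacuum
    with coarse-grained Langevin dynamics, and compares stage-by-stage CCS
    against ion-mobility mass-spectrometry measurements. Utilities for the
    experimental side (charge-ladder mass inference, travelling-wave ion
    mobility calibration, multi-wave-velocity averaging) and a synthetic
    Y-shaped antibody generator make every stage testable without external
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'radii.R'
    'ccs.R'
    'structure-io.R'
    'kinematics.R'
    'sampler.R'
    'collapse.R'
    'imms.R'
    'synthetic.R'
    'pipeline.R'
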