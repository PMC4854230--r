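Package: flexsmoc
Title: Hierarchical Flexible Fitting and Local SMOC Assessment of Atomic
    Models in Cryo-EM Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines atomic protein models into cryo-EM density maps in the
    2.5-4.5 Angstrom regime by hierarchical rigid-body and all-atom simulated
    annealing under stereochemical restraints, and assesses the local fit with
    the segment-based Manders' overlap coefficient (SMOC).  Provides MRC/CCP4
    map input and output, model-derived density simulation, B-factor map
    sharpening, global cross-correlation, RIBFIND-style clustering of
    secondary-structure elements into rigid bodies, per-residue SMOC profiles
    with Z-score outlier flagging, and SMOC-ranked loop-ensemble selection.
    A synthetic-fixture generator (ideal helices, helix hairpins, two-domain
    hinge proteins) with hinge/translation/loop perturbations and simulated
    target maps makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
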