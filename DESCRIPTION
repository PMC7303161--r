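Package: rvkinergy
Title: Right Ventricular Blood-Flow Kinetic Energy from 4D Flow Cardiac MR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification of right-ventricular (RV) intra-cavity blood-flow
    kinetic energy from time-resolved three-directional (4D flow) cardiac MR
    velocity fields. Provides velocity-field preprocessing (phase-aliasing
    unwrapping, magnitude-weighted local phase-offset correction, rigid
    cine-to-flow alignment), a time-resolved cylindrical RV mesh built from
    short-axis endocardial contours with voxel membership, per-phase kinetic
    energy curves normalized to end-diastolic volume with systolic/diastolic
    and E/A-wave summary parameters, retrospective valve-tracking tricuspid
    through-plane flow, cohort statistics (Spearman associations, Kruskal-
    Wallis with Dunn post-hoc letters, forward-conditional regression, Lin's
    concordance and coefficient of variability), and an analytic flow-phantom
    and cohort simulator with closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
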