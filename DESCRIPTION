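Package: spatialTME
Title: Spatial Analysis of the T-Cell Microenvironment in Multiplex
    Single-Cell Tissue Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the spatial immune microenvironment of
    solid tumors from multiplex immunofluorescence single-cell tables:
    marker-based gating of T-cell subpopulations (Tc1/Tc2/Tc17/Treg/Tfh
    and helper counterparts, dendritic and NK cells), per-sample
    composition and density profiles, contact-graph cell-cell interaction
    statistics with a label-permutation null, DBSCAN-based T-cell nest
    detection with Eps calibration, tumor-center versus invasive-margin
    zoning, cohort-level group comparison (volcano logic) and KNN-density
    (X-shift-style) patient clustering for immune-phenotype subgroup
    discovery. Includes a synthetic tissue generator (Poisson and
    parent-offspring cluster point processes with ground-truth sidecars)
    for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
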