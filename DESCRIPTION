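Package: BioavailQSPR
Title: QSPR Modeling of Percent Oral Bioavailability from Molecular
    Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts percent oral bioavailability (%F) of drug-like
    molecules from computed structural descriptors. Implements a
    topological/electronic/geometric descriptor set (single and aromatic
    bond counts, oxygen and nitrogen counts and fractions, maximum
    hydrogen partial charge, cube root of the gravitational index,
    mean hydrogen-bond-acceptor surface area, YZ shadow projection and
    an area-weighted acceptor surface charge), a sphere-exclusion
    rational train/test splitter, bivariate confidence-ellipse and
    decision-tree absorption classifiers in the (AlogP, PSA) plane, and
    a general regression neural network (Gaussian kernel regression)
    for the %F response, together with a synthetic-data generator that
    emulates a drug-like descriptor table for end-to-end testing.
    Molecule preparation (3D embedding, Gasteiger charges, Crippen logP,
    topological polar surface area) is delegated to RDKit through a
    bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr,
    knitr
SystemRequirements: Python (>= 3.9) with the RDKit package available on
    the executable found by Sys.which("python") (configurable via
    options(BioavailQSPR.python = ...)).
Config/testthat/edition: 3
RoxygenNote: 7.3.3
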