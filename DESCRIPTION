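Package: lvfiber
Title: Multiscale Left-Ventricle Mechanics with Stress-Driven Fiber Remodeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A closed-loop multiscale simulator of the human left ventricle
    (LV) for studying myocardial fiber remodeling in hypertrophic
    cardiomyopathy (HCM).  Couples an incompressible mixed finite-element
    model of an idealized ellipsoidal LV (transversely isotropic Guccione
    passive law plus an exponential myofiber spring) to a half-sarcomere
    cross-bridge contraction model (thin-filament activation and
    SRX/DRX/force-generating myosin kinetics on a strain grid) and a
    seven-compartment Windkessel systemic circulation.  A stress-based
    reorientation law incrementally rotates the reference fiber direction
    toward the local traction vector, and perturbation generators create
    heterogeneous hypercontractile, hypocontractile, or fibrous regions at a
    target volume fraction.  Postprocessing utilities compute
    pressure-volume metrics, helical/transverse fiber angles, angular
    deviation (disarray) in epicardial/endocardial layers, and systolic
    strain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
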