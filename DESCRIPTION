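Package: autosas
Title: Automated Small-Angle Scattering Model Fitting, Selection and Phase Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits a small expert-defined pool of constrained small-angle
    scattering (SAS) form-factor models (Guinier, sphere with radius
    polydispersity, polydisperse Gaussian coil, and a coil+sphere mixed
    model) to reduced 1-D scattering curves by bounded Levenberg-Marquardt
    weighted least squares, selects the best model per curve by
    information-theoretic criteria (lowest chi-squared, a modified Occam's
    razor, AIC, and a Laplace-evidence probabilistic method) with a
    "none of the above" goodness-of-fit gate, and converts the selected
    models into phase labels and structural descriptors (radius of
    gyration, micelle fraction, critical-micelle-concentration and
    micelle-conversion-threshold boundaries) over a solution-composition
    grid.  Includes Gaussian instrument-resolution smearing, a
    derivative-similarity spectral-clustering reference classifier, and a
    seeded synthetic-data generator for surfactant/preservative phase
    diagrams with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
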