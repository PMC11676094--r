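Package: nmrstress
Title: NMR Metabolomics of Restraint Stress: Binning, OPLS-DA and Enzyme
    Assay Calculations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end 1H-NMR metabolomics workflow built around an acute
    restraint-stress rat study design (6 non-stressed vs 7 stressed animals).
    Provides a synthetic spectrum generator with Lorentzian metabolite
    multiplets and known group effects, spectral preprocessing (peak-position
    calibration, 0.005-ppm binning, matrix-specific exclusion windows, total
    area and probabilistic quotient normalization), from-scratch PCA and
    OPLS-DA with Pareto scaling, venetian-blind cross-validated Q2, per-bin
    correlation and covariance loadings with a Pearson critical-value cutoff
    for discriminating-metabolite selection, and closed-form biochemical
    calculations: xanthine oxidoreductase enzyme activity from 290-nm
    absorbance changes, pooled-variance t-tests from group summary
    statistics, and 2^-ddCt relative gene expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
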