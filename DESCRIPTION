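Package: duopls
Title: Dual-Optimized Partial Least Squares Calibration for NIR Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating near-infrared spectroscopy (NIRS)
    calibration models for lignocellulosic feedstocks, with joint optimization of
    sample-subset partitioning and wavelength selection. Includes a synthetic
    spectra generator for two-class bioenergy sorghum populations (Gaussian band
    library, Beer-Lambert mixing, scatter/baseline/noise distortions), spectral
    preprocessing (multiplicative scatter correction, Norris smoothing, gap first
    derivative), Kennard-Stone and SPXY calibration/validation partitioning,
    NIPALS PLS1 regression with leave-one-out cross-validation, outlier removal
    and the full RMSEC/RMSECV/RMSEP/R2/RPD/RER metric suite, five wavelength
    selection algorithms (CARS, selectivity ratio, VIP, UVE, MC-UVE) with
    consensus categorization, PCA plus Mahalanobis-distance linear discriminant
    classification, and theoretical ethanol yield computation from hexose and
    pentose sugar pools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
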