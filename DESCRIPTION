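Package: dustspec
Title: Estimating Foliar Dust Retention from Leaf Hyperspectral Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying particulate dust deposited on plant leaves
    from laboratory reflectance spectra (350-2500 nm). Implements spectral
    preprocessing (resampling, Savitzky-Golay smoothing, first derivatives),
    red/blue/yellow edge ("trilateral") parameter extraction, five narrow-band
    vegetation indices (LWI, REI, NDI, SRI, PRI), per-band and per-parameter
    Pearson correlation screening against dust load, univariate linear
    calibration with ranking and held-out validation, and a seeded simulator of
    dusted-leaf spectra based on exponential-saturation coverage and linear
    spectral mixing, so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
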