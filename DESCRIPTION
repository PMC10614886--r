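Package: spindlemetrics
Title: Quantitative Metrics for Mitotic Spindle Fluorescence Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies kinesin-8 (KIF18A) function on the mitotic spindle
    from multi-channel fluorescence microscopy: chromosome-alignment
    full-width-at-half-maximum (FWHM) from boxed pole-to-pole kinetochore
    or DNA intensity profiles, motor localization relative to the spindle
    pole from wide line scans aligned on peak gamma-tubulin, time-lapse
    relocalization as a Final/Initial fluorescence ratio on a percent
    spindle-length axis with its area under the curve, mitotic-population
    counting statistics, proliferation fold change, and four-parameter
    logistic IC50 fitting of ATPase percent-inhibition dose-response data.
    Includes a synthetic-data generator that renders spindle images,
    time-lapse stacks, plate tables and growth curves with known ground
    truth so that every analysis stage is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    minpack.lm
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
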