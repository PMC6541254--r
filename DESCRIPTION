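Package: grapemx
Title: Non-Destructive Grape Ripening Indices and Optical-Sensor
    Investment Appraisal
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for non-destructive estimation of grape berry ripening
    from multi-channel chlorophyll-fluorescence readings and for the
    economic appraisal of adopting such a sensor.  Converts raw
    fluorescence channels into the five standard excitation-ratio indices
    (SFR_R, FLAV, FLAV_UV, ANTH_RG, FERARI), fits and inverts the
    calibration families relating indices to wet-chemistry ripening
    measures (linear, polynomial, sigmoid, with total-soluble-solids
    domain restriction, berry- vs skin-mass unit conversion and
    cluster-side concordance), and appraises sensor adoption by net
    present value: annual cost-saving cash flows from a sampling
    protocol, breakeven lifetime search, Monte Carlo uncertainty and
    sampling-time sensitivity.  A seeded synthetic-data module simulates
    seasonal ripening trajectories and fluorescence records consistent
    with published calibration equations so the full pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
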