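Package: csfdispersion
Title: Intrathecal Solute Dispersion Analysis for an In Vitro Cerebrospinal Fluid Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying intrathecal solute dispersion after lumbar
    injection in a bench-top cerebrospinal fluid (CSF) model of the cynomolgus
    monkey. Synthesizes combined cardiac plus respiratory CSF flow waveforms,
    builds axial slice-volume representations of the CSF space, simulates
    one-dimensional oscillatory-dispersion transport of a fluorescent tracer
    under configurable lumbar injection protocols, renders dual-exposure camera
    frames, converts image stacks to calibrated spatial-temporal concentration
    maps, and computes percent-injected-dose to the extra-axial (cranial) CSF,
    area-under-curve profiles, repeatability statistics (standard-deviation
    maps, Bland-Altman limits of agreement, percent of dynamic range), and
    unpaired t-test group contrasts across injection-parameter groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
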