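Package: pelvnav
Title: Landmark-Based Navigation Geometry for Percutaneous Sacroiliac Screw Placement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry and simulation toolkit for augmented-reality style,
    radiation-free navigation of percutaneous sacroiliac (SI) screws. Implements
    paired-point similarity registration (absolute orientation) of a planned
    pelvis model to probed anatomical landmarks (both anterior superior iliac
    spines and the pubic symphysis), drill-trajectory guidance as a replayable
    state machine, and the full screw-placement evaluation geometry: maximal
    lateral deviation with base/tip localisation, entry and central-aim point
    deviations, angular deviation, and cortical-perforation detection with
    anatomical direction classification. A parametric pelvis phantom with two
    S1 and two S2 osseous corridors per pelvis and a Monte-Carlo landmark-error
    engine allow the whole workflow to be exercised and validated in software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
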