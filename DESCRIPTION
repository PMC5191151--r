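Package: posturekit
Title: Posture, Gait and Event Monitoring from Multichannel Body-Worn Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses multichannel 3-axis accelerometer streams
    from a five-sensor instrumented vest (lower cervical spine, chest, lumbar
    centre of mass, and both sides of the waist). Provides a fixed-point
    integer-only CORDIC vectoring pipeline that converts raw 12-bit counts to
    pitch, roll and inclination angles; threshold-based classification of
    postures (standing, sitting, lying, leaning forward) and detection of
    alert-worthy events (sustained head-down and trunk-bend postures, falls,
    lying-to-sitting transitions); and bilateral-waist gait analysis (step
    detection, walking time, interval-based step symmetry index, forward lean)
    with long-term trend aggregation. A synthetic-data generator with a
    quantization and noise model of the sensor front end makes every stage
    testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
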