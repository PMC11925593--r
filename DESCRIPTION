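Package: pcrtwin
Title: Digital Twin of a Portable PCR Thermal Cycler
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates the thermal control loop of a portable, low-cost
    polymerase chain reaction (PCR) instrument: a linear temperature
    sensor read through a quantizing analog-to-digital converter, a
    gain-scheduled ("piecewise") PID controller driving an 8-bit
    pulse-width-modulated Peltier element, a lumped-parameter thermal
    model of the heating block and heated lid, and a protocol engine that
    runs complete thermal-cycling programs. Includes least-squares sensor
    calibration, plant calibration against ramp observables, performance
    metrics (ramp rates, hold accuracy, lid stability), ggplot2 graphics,
    and a small command-line interface.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
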