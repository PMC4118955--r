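Package: sleepdyn
Title: Sleep-Wake Regulation Models and Their Equivalence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulators and analysis tools for the two-process model of
    sleep regulation and the mutual-inhibition (VLPO/mono-aminergic)
    neuronal model, including the hard-switch reduction that maps the
    neuronal model exactly onto the two-process model, calibration of that
    reduction from the full sigmoid model, first-return maps of sleep-onset
    times with grazing-bifurcation analysis, parameter scans of monophasic
    and polyphasic sleep patterns, and wake-effort computation under sleep
    deprivation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
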