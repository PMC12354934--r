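Package: smartem
Title: Runtime Planning and Simulation for Smart Microscopy Acquisition
Version: 0.1.0
Authors@R: person("smartem", "developers", role = c("aut", "cre"),
    email = "smartem@example.org")
Description: Analytic runtime models for traditional, serial-smart and
    parallel-smart electron microscopy acquisition workflows, selection of
    the minimal rescan fraction meeting a quality standard via inversion of
    a monotone quality curve, a discrete-event simulation of the imaging
    and computation threads that validates the parallel analytic formula,
    one-at-a-time sensitivity sweeps, and a self-contained synthetic
    mixed-dwell-time image pipeline for empirical quality-curve estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
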