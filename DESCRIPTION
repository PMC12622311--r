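Package: dpcrval
Title: Duplex Digital PCR Quantification of GM Content and In-House Method
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Poisson partition statistics for digital PCR (lambda estimation
    with delta-method confidence intervals, copies per microlitre and per
    reaction), conversion of paired event-specific/reference-gene copy numbers
    into GM mass fractions via conversion factors, and the full in-house
    validation battery used for GMO quantification methods: trueness, precision
    (repeatability and intermediate precision), dynamic range, linearity,
    asymmetric limit of quantification, multifactorial robustness and expanded
    measurement uncertainty (k = 2), with ENGL-style acceptance thresholds.
    Includes a synthetic partition-level data generator emulating droplet and
    nanoplate platform regimes (three-population fluorescence amplitudes with
    "rain", no-template-control contamination, multi-run replicate designs) so
    the whole pipeline is testable without instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
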