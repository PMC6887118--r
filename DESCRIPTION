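Package: mitoaxon
Title: Quantification of Mitochondrial Fission, Transport and Actin-Patch
    Colocalization Along Sensory Axons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for timelapse fluorescence imaging of
    mitochondria along quasi-1D axons. Converts annotated stacks into
    calibrated kymograph profiles, segments and links mitochondria,
    calls fission and fusion events from intensity and separation
    criteria, classifies transport (stalled, oscillating, transported)
    and decomposes it into runs with velocities and direction switches,
    detects transient actin patches and Drp1 accumulations, computes
    the random-overlap probability statistic for patch-fission
    colocalization, and quantifies immunofluorescence intensity and
    FRAP recovery. Includes an event-driven stochastic simulator of
    axonal mitochondria with a microscope-like renderer and exact
    ground-truth logs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
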