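Package: phycoMS
Title: MALDI-TOF Mass Spectral Fingerprinting of Microalgae and Their Mixtures
Version: 0.1.0
Authors@R: person("AzCATI", "Pipeline Maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to turn linear-mode MALDI-TOF profile spectra of microalgae
    into strain fingerprints and to compare those fingerprints with 18S rDNA
    sequence data. Covers spectrum preprocessing (Savitzky-Golay smoothing,
    TopHat morphological baseline subtraction, robust noise estimation, mass
    calibration, burst quality gating), centroid peak detection with
    signal-to-noise filtering, +/- 2 m/z peak matching, all-replicate consensus
    and composite fingerprints, Pearson/UPGMA similarity clustering with
    pseudo-gel rendering, classification of peaks in mixed-culture spectra as
    constituent-derived, suppressed, or mixture-specific, Kimura two-parameter
    distances with neighbor-joining trees, and a ground-truth-retaining
    synthetic spectrum and sequence simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    ape,
    phangorn,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
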