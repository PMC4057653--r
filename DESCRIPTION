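Package: binopupil
Title: Binocular Pupillometry: Segmentation, Stimulus Generation and
    Phantom Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for video-based binocular pupillometry. Implements a
    five-stage pupil image analysis pipeline (median smoothing, mean-intensity
    thresholding, morphological closing and hole filling, boundary extraction,
    direct least-squares ellipse fitting), per-eye pupil trace processing with
    blink-artifact removal and pixel-to-millimeter calibration, a light
    stimulus waveform and trigger-timeline generator, a ground-truthed pupil
    light reflex simulator that renders synthetic eye videos, and a
    phantom-based validation protocol measuring accuracy, repeatability and
    linear resolution of the measurement chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
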