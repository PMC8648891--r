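Package: betaburst
Title: Transient Beta-Burst Detection and Burst-Locked EEG/fMRI Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transient beta bursts in continuous electrophysiological
    time courses as suprathreshold local maxima of a smoothed Morlet-wavelet
    spectrogram, quantifies post-movement beta rebound (PMBR) and
    load-dependent burst rates around an n-back task schedule, and estimates
    burst-locked BOLD correlates with an impulse-regressor general linear
    model using a canonical double-gamma hemodynamic response function. A
    bundled synthetic-data generator produces ground-truth-labelled EEG,
    behavioural event schedules and BOLD series with the statistical
    structure the analysis assumes, so every stage is testable without
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
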