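Package: zfrfc
Title: Zero-Frequency Resonator Detection of Spontaneous BOLD Events and
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects spontaneous blood-oxygen-level-dependent (BOLD) events in
    resting-state fMRI time courses with a zero-frequency resonator (ZFR): the
    series is passed through a second-order resonator with both poles at zero
    frequency, the local mean is removed, and positive zero crossings mark event
    onsets. Detected onsets drive static functional-connectivity maps
    (conditional-rate maps and high-SNR segment correlation maps) and dynamic
    coactivation-pattern (CAP) analysis via k-means clustering of fMRI frames
    with cosine distance, including cluster-stability (Jaccard), dwell-time and
    fractional-occupancy summaries. A SimTB-style synthetic resting-state
    generator (spatial components, HRF-convolved event trains, Rician noise at
    controlled contrast-to-noise ratios) provides ground-truth test beds.
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
    purrr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
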