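Package: eegkan
Title: Kolmogorov-Arnold Network Classifiers for Scalp-EEG Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained pipeline for detecting epileptic seizures in
    multichannel scalp EEG with shallow Kolmogorov-Arnold networks (KANs):
    networks whose edges carry learnable B-spline activation functions
    instead of fixed node nonlinearities. Provides a from-scratch KAN
    implementation (spline basis, analytic gradients, Adam training,
    checkpointing), an EEG front-end (12-second segmentation, FastICA-based
    eye-blink removal screened by Pearson correlation with the fronto-polar
    channels, short-time Fourier transform featurization), a seeded
    synthetic-EEG generator with seizure and blink injection plus an
    out-of-distribution variant, a training and evaluation harness with
    AUROC-plateau weight selection, and EDF/EDF+ input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    signal,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
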