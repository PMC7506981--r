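Package: emgaug
Title: Data Augmentation for Surface Electromyography Gesture Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Label-preserving data augmentation for multichannel surface
    electromyography (sEMG) gesture recordings. Implements five augmentation
    methods operating on RMS-envelope signals: additive Gaussian noise at a
    target signal-to-noise ratio, magnitude warping with random cubic-spline
    curves, wavelet-decomposition perturbation of detail coefficients, and two
    generative sEMG simulators (a shaping-filter model with covariance-matched
    multichannel carriers, and an inverse-gamma variance model fitted by
    expectation maximization). Provides stochastic composition policies
    (one / all / random), augmentation-ratio bookkeeping, sliding-window
    segmentation into fixed-size images, repetition-based train/validation/test
    splitting, class balancing, dataset preprocessing chains (RMS envelope,
    Butterworth low-pass, notch, band-pass, resampling), silhouette and
    Davies-Bouldin cluster-quality metrics with auditable intermediates, a
    deterministic synthetic-fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    signal,
    stats,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
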