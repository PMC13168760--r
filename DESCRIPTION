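Package: pillarforce
Title: Contractile Force, Orientation and Compaction Analysis for
    Pillar-Based Muscle Microtissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for engineered skeletal-muscle
    microtissues suspended between two compliant force-sensing pillars.
    Converts microscope image sequences into calibrated contractile forces
    via Euler-Bernoulli beam mechanics for elliptical cantilevers, computes
    a cosine-weighted fiber orientation index from Fourier directionality
    histograms, tracks pillar centroids to obtain deflection and
    interpillar-distance (compaction) traces, extracts twitch and tetanic
    metrics under electrical-stimulation protocols, summarises
    dose-response experiments with effect sizes, and models the
    stimulation-chamber electric field with an analytic estimate and a
    finite-difference Laplace solver. A synthetic-data module generates
    every input with ground-truth sidecars so the full pipeline is testable
    without raw microscopy data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
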