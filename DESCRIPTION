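Package: pulseveil
Title: Concealing Remote Photoplethysmography Signals in Facial Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for privacy-preserving modification of facial video to
    conceal the remote photoplethysmography (rPPG) signal, together with the
    full estimation and evaluation stack used to grade concealment. Provides
    eleven lightweight per-frame modification operators (median, Gaussian and
    bilateral blurring; cumulative and sliding-window temporal averaging; six
    noise-injection methods) applied inside landmark-derived regions of
    interest; five classical blood-volume-pulse extraction algorithms (GREEN,
    ICA, CHROM, POS, LGI) with Welch spectral-peak heart-rate estimation;
    evaluation metrics (heart-rate error, frame information loss, overall
    trade-off score, throughput); and a synthetic pulse-modulated scene
    generator with co-registered ground-truth PPG so the whole pipeline is
    exercisable without external datasets. Lossless frame persistence is used
    throughout because compression confounds concealment measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    png,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
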