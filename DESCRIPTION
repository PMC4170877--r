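Package: pcboot
Title: Partial-Bootstrap Validation of Principal Component Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validation tools for Principal Components Analysis based on the
    partial bootstrap: resampled observations are projected as supplementary
    points onto the original loading basis, yielding per-object clouds of
    replicate scores that are summarised by convex confidence polygons
    (shoelace areas, signed-area centroids), bootstrap eigenvalue bands for
    choosing the number of nontrivial axes, and average-linkage dendrograms
    comparing original scores with polygon centroids. Includes a
    single-channel EEG spectral and time-domain feature extraction front-end
    (Butterworth filtering, epoching, Bartlett averaged periodograms, band
    maxima and trapezoidal band powers) and synthetic-data generators for
    fully reproducible, data-free testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
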