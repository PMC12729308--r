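Package: gazetone
Title: Gaze-Conditioned Sonification of Artworks and Eye-Tracking Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns a child's gaze over a painting into a short piano melody and
    analyses the eye-tracking record along the way. Images are decomposed into a
    10 x 10 colour grid, each cell's dominant colour is mapped to a MIDI pitch
    through a configurable hue/value matrix anchored at pure red = middle C,
    fixations are detected with a dispersion (I-DT) algorithm, gaze hotspots
    seed an autoregressive LSTM melody generator, and generated sequences are
    quantized, range-clamped and written as Standard MIDI Files. Also includes
    summary-statistic group comparisons (pooled-SD Cohen's d, t-tests,
    Bonferroni thresholds, percent changes) for fixation-duration and
    area-of-interest metrics, and seeded synthetic-data generators for every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
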