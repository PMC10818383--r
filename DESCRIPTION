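Package: tscstune
Title: Calibration of Transcutaneous Spinal Cord Stimulation from
    Mechanomyography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tuning transcutaneous spinal cord stimulation
    (tSCS) from evoked muscle responses. Raw electromyography (EMG) and
    skin-normal acceleration (mechanomyography, MMG) sweeps recorded
    during a double/single-pulse calibration protocol are averaged,
    validated, and classified into no-response, reflex and direct
    muscular response classes from the EMG amplitude and paired-pulse
    suppression characteristics. A feature table is extracted from the
    acceleration signals and used in leave-one-subject-out supervised
    classification (random forest, support vector machine, linear
    discriminant analysis) with nested random hyperparameter search and
    balanced accuracy scoring. Per-subject therapy parameters (electrode
    position and sub-motor stimulation current) are identified from the
    class grids with a nested rule cascade, and the agreement between
    EMG-derived and classifier-derived parameters is quantified. A
    synthetic evoked-response cohort generator with known ground truth
    makes the whole pipeline testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    ranger,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
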