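Package: trapcam
Title: Trap-Camera Image Analysis and Capture Statistics for Fruit-Fly
    Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated counting of insects on the surfaces of
    attractant-baited traps from time-lapse camera imagery, built around a
    field-cage study of Mediterranean fruit fly (Ceratitis capitata) landing
    and capture on Jackson traps with and without a DDVP insecticide strip.
    Implements the detection pipeline (weighted-average background
    subtraction, 8-bit conversion, Otsu or fixed thresholding, binary
    open/close blobbing, and area-gated particle analysis), validation of
    automatic against manual counts (discrepancy fractions and Pearson
    correlation), and the capture statistics (Table-style summaries, one-way
    and two-way ANOVA with interaction, Fisher LSD post hoc comparisons, and
    Kolmogorov-Smirnov normality checks on log-transformed counts). A seeded
    synthetic trap-camera simulator provides image sequences with exact blob
    ground truth and overdispersed capture-count tables so that every stage
    is testable without raw field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    car,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
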