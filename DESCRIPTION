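Package: urodyn
Title: Voiding Spot Assay and Cystometry Analysis for Small-Animal
    Urodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for sub-chronic neuromodulation studies of
    stress urinary incontinence in small-animal models.  Detects and
    classifies urine spots (voids, leaks, excluded splatter) on absorbent
    pad images; preprocesses cystometrogram pressure recordings
    (zero-phase Butterworth low-pass, drift removal, syringe-pump
    correction), segments filling cycles and extracts urodynamic
    parameters (normalized storage pressures, leak point volume and
    pressure, voiding efficiency); aggregates daily micturition metrics
    into per-animal period summaries and baseline-vs-treatment change
    scores; represents intermittent stimulation protocols; and applies a
    normality-gated statistical workflow (ROUT outlier exclusion,
    Shapiro-Wilk gate, paired t / Wilcoxon, Welch t / Mann-Whitney,
    Brown-Forsythe and Welch ANOVA with Dunnett T3, Kruskal-Wallis with
    Dunn's test).  Synthetic-data generators with known ground truth make
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    jsonlite,
    png,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
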