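Package: miiseg
Title: Chromosome Segregation Analysis for Meiosis II Live-Imaging Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of 4D centromere tracks from live-imaged
    mouse oocytes undergoing the second meiotic division: cubic smoothing-spline
    track denoising, spindle coordinate-frame estimation from sister-centromere
    orientations, per-chromosome metaphase-II metrics (inter-centromere distance,
    chromosome-axis angle and distances, speed), anaphase-II onset detection,
    lagging-chromatid timing, segregation-pattern classification, aneuploidy
    calling, cohort statistics (Welch t, Mann-Whitney, chi-squared, nested
    ANOVA), and a per-1000-chromosome attachment-fate extrapolation. Includes a
    synthetic oocyte-recording generator with known ground truth emulating
    young-adult and aged cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
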