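Package: hodasym
Title: Quantitative Detection of Hypertrophic Olivary Degeneration from
    Medullary Intensity Asymmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects hypertrophic olivary degeneration (HOD) from the
    left/right intensity asymmetry of the anterior medulla oblongata on
    PD-weighted, T2-weighted and FLAIR MRI, and from lateralized changes
    in DTI-derived fractional anisotropy (FA) and mean diffusivity (MD).
    Implements landmark-driven quadrant segmentation of the medulla, the
    unsigned percentage asymmetry index, a control-cohort-calibrated
    detection threshold (mean + 2.576 * SD), Fleiss' kappa interrater
    agreement with per-rater diagnosis and false-positive rates, and the
    accompanying statistical comparisons (Lilliefors normality screening,
    paired and Welch t-tests, Wilcoxon-Mann-Whitney). A synthetic
    brainstem phantom generator with known ground truth provides cohorts
    for end-to-end exercise of the pipeline without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
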