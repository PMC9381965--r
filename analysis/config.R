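# Shared study configuration for the analysis scripts (run from the
# repository root). Desk-scale cohort mirroring the motivating study:
# 15 patients with Guillain-Mollaret-triangle lesions, 15 disease
# controls, three blinded reviewers.

library(hodasym)

STUDY_SEED <- 2026L

study_spec <- function() {
  cohort_spec(n_patients = 15L, n_controls = 15L, seed = STUDY_SEED)
}

study_raters <- function() default_raters(STUDY_SEED)

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}
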