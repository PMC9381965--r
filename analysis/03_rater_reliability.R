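#!/usr/bin/env Rscript
# Step 3: reviewer-based analysis. Simulates three blinded raters over
# the cohort, then computes Fleiss' kappa, per-rater diagnosis rates,
# false-positive rates (controls: any positive; patients: wrong-side
# positives) and the consensus rate per modality. Writes
# results/ratings.csv and results/rater_reliability.csv.

source("analysis/config.R")

spec <- study_spec()
out <- results_dir()
plan <- cohort_plan(spec)
meta <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i)
  hodasym:::subject_meta_from_plan(plan[i, ])))

ratings <- simulate_raters(plan, study_raters(), meta)
write_ratings(ratings, file.path(out, "ratings.csv"))

rows <- list()
for (m in c("PD", "T2", "FLAIR")) {
  kap <- fleiss_kappa(ratings, m, subjects = meta)
  diag_p <- diagnosis_rates(ratings, meta, m, "patient")
  diag_c <- diagnosis_rates(ratings, meta, m, "control")
  fp <- false_positive_rates(ratings, meta, m)
  cat(sprintf(
    "%-5s kappa %.2f | patient diagnosis %.1f%% (%.1f-%.1f), consensus %.1f%% | control FP %.1f%%, patient wrong-side %.1f%%\n",
    m, kap$kappa, diag_p$mean_diagnosis_pct,
    diag_p$range_diagnosis_pct[1], diag_p$range_diagnosis_pct[2],
    diag_p$consensus_pct, fp$control$mean_pct, fp$patient$mean_pct))
  rows[[m]] <- data.frame(
    modality = m, fleiss_kappa = kap$kappa,
    patient_diagnosis_mean_pct = diag_p$mean_diagnosis_pct,
    patient_diagnosis_min_pct = diag_p$range_diagnosis_pct[1],
    patient_diagnosis_max_pct = diag_p$range_diagnosis_pct[2],
    patient_consensus_pct = diag_p$consensus_pct,
    control_diagnosis_mean_pct = diag_c$mean_diagnosis_pct,
    control_fp_mean_pct = fp$control$mean_pct,
    patient_wrong_side_mean_pct = fp$patient$mean_pct
  )
}
write.csv(do.call(rbind, rows), file.path(out, "rater_reliability.csv"),
          row.names = FALSE)
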