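#!/usr/bin/env Rscript
# Simulate the study cohort: 7 young (YA) and 7 old (OA) subjects, each with
# a gated cine phase-contrast acquisition of the arterial slice (basilar
# trunk + both internal carotids, VENC 50 cm/s) and the venous slice
# (superior sagittal + straight sinus, VENC 20 cm/s). Writes the subject
# table and the ground-truth per-vessel volumes/peaks for later comparison.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE)[1])),
                 "00_config.R"))

cohort <- load_cohort()

subjects <- do.call(rbind, lapply(cohort, function(b) {
  data.frame(subject_id = b$spec$subject_id, age_group = b$spec$age_group,
             sex = b$spec$sex, weight_g = round(b$spec$weight_g),
             heart_rate_bpm = round(b$spec$heart_rate_bpm, 1),
             rr_ms = round(rr_interval_ms(b$spec), 1),
             gm_ul = round(b$spec$gm_ul), wm_ul = round(b$spec$wm_ul),
             csf_ul = round(b$spec$csf_ul),
             n_frames = length(b$arterial$frame_times_ms),
             coverage = round(max(b$arterial$frame_times_ms) /
                              b$arterial$rr_ms, 3))
}))
write.csv(subjects, file.path(RESULTS_DIR, "01_subjects.csv"),
          row.names = FALSE)

truth <- do.call(rbind, lapply(cohort, function(b) {
  do.call(rbind, lapply(c("arterial", "venous"), function(sl) {
    tr <- b$truth[[sl]]
    data.frame(subject_id = b$spec$subject_id, vessel = names(tr$volumes_ul),
               true_volume_ul = unname(tr$volumes_ul),
               true_peak_pct_cc = unname(tr$peak_pct_cc))
  }))
}))
write.csv(truth, file.path(RESULTS_DIR, "01_ground_truth.csv"),
          row.names = FALSE)

cat(sprintf(
  "Simulated %d subjects (%d YA, %d OA); HR %d-%d bpm, %d-%d frames,\n",
  nrow(subjects), N_YOUNG, N_OLD, round(min(subjects$heart_rate_bpm)),
  round(max(subjects$heart_rate_bpm)), min(subjects$n_frames),
  max(subjects$n_frames)),
  sprintf("cycle coverage %.0f-%.0f%%. Tables: 01_subjects.csv, 01_ground_truth.csv\n",
          100 * min(subjects$coverage), 100 * max(subjects$coverage)))
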