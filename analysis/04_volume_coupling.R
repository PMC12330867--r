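#!/usr/bin/env Rscript
# Integrate the 32-step profiles into per-cycle blood volumes; compute
# perfusion, drainage and CBF; and analyse arterio-venous coupling under the
# Monro-Kellie constraint: venous correction factor CF, step-wise and
# cumulative Art - CF*Ven balance, oscillating volume (peak-to-peak of the
# cumulative curve), and the arterial-venous flow hysteresis loop area.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE)[1])),
                 "00_config.R"))

cohort <- load_cohort()
res <- analyze_cohort(cohort)

haemo <- do.call(rbind, lapply(res$subjects, function(s) {
  h <- s$haemo
  data.frame(subject_id = h$subject_id, age_group = h$age_group,
             t(h$volumes_ul), t(h$totals_ul),
             BT_pct = h$fractions$BT_pct, carotids_pct = h$fractions$carotids_pct,
             SS_pct = h$fractions$SS_pct,
             perfusion_ml_min = h$perfusion_ml_min,
             drainage_ml_min = h$drainage_ml_min,
             cbf_ml_min_100g = h$cbf_ml_min_100g, CF = h$CF,
             oscillating_volume_ul = h$oscillating_volume_ul,
             osc_pct_csf = h$osc_pct_csf,
             hysteresis_area = h$hysteresis_area)
}))
rownames(haemo) <- NULL
write.csv(haemo, file.path(RESULTS_DIR, "04_haemodynamics.csv"),
          row.names = FALSE)

balance <- do.call(rbind, lapply(res$subjects, function(s) {
  h <- s$haemo
  data.frame(subject_id = h$subject_id, age_group = h$age_group, step = 1:32,
             balance_ul = h$balance_ul,
             cumulative_balance_ul = h$cumulative_balance_ul,
             art_flow_ul_s = s$profiles$Art$flow_ul_s,
             ven_flow_ul_s = s$profiles$Ven$flow_ul_s)
}))
rownames(balance) <- NULL
write.csv(balance, file.path(RESULTS_DIR, "04_balance_loops.csv"),
          row.names = FALSE)

gmean <- function(col, g) round(mean(haemo[[col]][haemo$age_group == g]), 2)
cat(sprintf("Perfusion: %.1f (YA) vs %.1f (OA) ml/min; CBF %.0f vs %.0f ml/min/100g.\n",
            gmean("perfusion_ml_min", "YA"), gmean("perfusion_ml_min", "OA"),
            gmean("cbf_ml_min_100g", "YA"), gmean("cbf_ml_min_100g", "OA")),
    sprintf("CF %.1f vs %.1f; oscillating volume %.1f vs %.1f ul (%.2f%% vs %.2f%% of CSF);\n",
            gmean("CF", "YA"), gmean("CF", "OA"),
            gmean("oscillating_volume_ul", "YA"),
            gmean("oscillating_volume_ul", "OA"),
            gmean("osc_pct_csf", "YA"), gmean("osc_pct_csf", "OA")),
    sprintf("hysteresis area %.0f vs %.0f (ul/s)^2 (OA/YA ratio %.2f).\n",
            gmean("hysteresis_area", "YA"), gmean("hysteresis_area", "OA"),
            gmean("hysteresis_area", "OA") / gmean("hysteresis_area", "YA")),
    "Tables: 04_haemodynamics.csv, 04_balance_loops.csv\n")
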