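#!/usr/bin/env Rscript
# Group-level statistics: mean +/- SD summary per metric and age group, exact
# nonparametric young-vs-old comparisons (Mann-Whitney, with Bonferroni
# correction over the volume family), and the sex-by-age Fisher association.
# Writes the summary table, the test results and a markdown digest.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE)[1])),
                 "00_config.R"))

cohort <- load_cohort()
res <- analyze_cohort(cohort)

write.csv(res$summary, file.path(RESULTS_DIR, "05_summary.csv"),
          row.names = FALSE)

vol_metrics <- c("volume_BT", "volume_RC", "volume_LC", "volume_SS",
                 "volume_StS", "volume_arteries", "volume_sinuses")
other_metrics <- c("perfusion_ml_min", "cbf_ml_min_100g", "CF",
                   "oscillating_volume_ul", "hysteresis_area",
                   "peak_pct_Art", "upslope_BT")
vol_tests <- bonferroni(lapply(vol_metrics, function(m)
  compare_groups(res$table, m)))
other_tests <- lapply(other_metrics, function(m) compare_groups(res$table, m))
tests <- c(vol_tests, other_tests)
test_df <- do.call(rbind, lapply(tests, function(t)
  data.frame(metric = t$metric, test = t$test, n1 = t$n1, n2 = t$n2,
             statistic = t$statistic, p_raw = t$p_raw,
             p_adjusted = t$p_adjusted, adjust = t$adjust)))
write.csv(test_df, file.path(RESULTS_DIR, "05_group_tests.csv"),
          row.names = FALSE)

sex <- table(vapply(cohort, function(b) b$spec$age_group, ""),
             vapply(cohort, function(b) b$spec$sex, ""))
fisher <- if (all(dim(sex) == c(2, 2)) && all(colSums(sex) > 0)) {
  fisher_association(unclass(sex))
} else NULL

md <- c("# Young vs old synthetic cohort — group comparison",
        "", "| metric | YA mean±SD | OA mean±SD | p (MW) | p adj |",
        "|---|---|---|---|---|")
fmt <- function(m, g) {
  r <- res$summary[res$summary$metric == m & res$summary$age_group == g, ]
  sprintf("%.2f ± %.2f", r$mean, r$sd)
}
for (t in tests) {
  md <- c(md, sprintf("| %s | %s | %s | %.3f | %.3f |", t$metric,
                      fmt(t$metric, "YA"), fmt(t$metric, "OA"),
                      t$p_raw, t$p_adjusted))
}
if (!is.null(fisher))
  md <- c(md, "", sprintf("Sex-by-age Fisher exact test: p = %.3f.",
                          fisher$p_raw))
writeLines(md, file.path(RESULTS_DIR, "05_group_stats.md"))

sig <- test_df$metric[test_df$p_raw < 0.05]
cat("Group tests done.",
    if (length(sig)) paste("Raw p < 0.05 for:", paste(sig, collapse = ", "))
    else "No metric reached raw p < 0.05 at n = 7 + 7.",
    "\nTables: 05_summary.csv, 05_group_tests.csv, 05_group_stats.md\n")
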