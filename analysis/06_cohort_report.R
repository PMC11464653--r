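#!/usr/bin/env Rscript
# Full pipeline over the cohort: per-animal record assembly, paired
# baseline-vs-post summaries, CRALE flags, and the cross-modality
# associations (lung weight vs Crs, delta-Pes vs lung weight, CT vs
# ex-vivo weight, weight vs wet-to-dry).
source("analysis/00_config.R")

cohort <- make_cohort()
report <- run_pipeline(cohort)
write_cohort_report(report, file.path(RESULTS_DIR, "cohort_report"))

message(sprintf("CRALE: %d/%d animals post-CPR (baseline %d)",
                report$n_crale_post, nrow(report$records),
                report$n_crale_base))
for (a in report$associations) {
  message(sprintf("  %s vs %s: r = %.3f (p = %.3g)",
                  a$pair[1], a$pair[2], a$r, a$p))
}
pc <- report$paired
message(sprintf("Paired change: weight +%.0f g (p = %.3g); Crs %.1f -> %.1f (p = %.3g)",
                pc$weight$mean_diff, pc$weight$p,
                pc$crs$mean_baseline, pc$crs$mean_post, pc$crs$p))
message("Report written under results/cohort_report/")
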