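#!/usr/bin/env Rscript
# Point-counting stereology on each animal's histology label image plus
# the necropsy ratios (wet-to-dry, lung/body weight).
source("analysis/00_config.R")

cohort <- make_cohort()

rows <- lapply(cohort$animals, function(a) {
  h <- a$histology
  grid <- overlay_grid(ncol(h$image), nrow(h$image), 100)
  pc <- point_count(h$image, grid, h$legend)
  data.frame(
    id = a$id,
    airspace_pct = pc$percent[["airspace"]],
    acinar_pct = pc$percent[["acinar_tissue"]],
    nonacinar_pct = pc$percent[["nonacinar_tissue"]],
    hemorrhage_pct = pc$percent[["hemorrhage"]],
    alveolar_tissue_pct = pc$alveolar_tissue_percent,
    true_airspace_pct = 100 * h$truth$fractions[["airspace"]],
    wet_to_dry = wet_to_dry(a$necropsy$wet_g, a$necropsy$dry_g),
    lung_body_g_kg = lung_body_ratio(a$necropsy$exvivo_weight_g,
                                     a$necropsy$body_kg))
})
st <- do.call(rbind, rows)
write.csv(st, file.path(RESULTS_DIR, "stereology.csv"), row.names = FALSE)

message(sprintf("Airspace %.0f%%, tissue %.0f%%, hemorrhage %.0f%% (point counts, 100 points)",
                mean(st$airspace_pct), mean(st$acinar_pct + st$nonacinar_pct),
                mean(st$hemorrhage_pct)))
message(sprintf("Point-count vs pixel truth (airspace): max |err| %.1f points",
                max(abs(st$airspace_pct - st$true_airspace_pct))))
message(sprintf("Wet-to-dry %.1f; lung/body %.1f g/kg",
                mean(st$wet_to_dry), mean(st$lung_body_g_kg)))
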