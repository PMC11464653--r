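#!/usr/bin/env Rscript
# Generates the five-animal synthetic cohort (baseline + post-CPR CT
# phantoms, CPR pressure waveforms with occlusion maneuvers, blood-gas
# panels, histology label images, necropsy values) and records the
# generator ground truth per animal.
source("analysis/00_config.R")

cohort <- make_cohort()

truths <- do.call(rbind, lapply(cohort$animals, function(a) {
  data.frame(
    id = a$id, severity = a$severity,
    true_weight_base_g = a$baseline_ct$truth$weight_g,
    true_weight_post_g = a$post_ct$truth$weight_g,
    true_gas_base_ml = a$baseline_ct$truth$gas_volume_ml,
    true_gas_post_ml = a$post_ct$truth$gas_volume_ml,
    true_cl_base = a$cl_base, true_cl_post = a$cl_post, true_ccw = a$ccw,
    true_shunt_min15 = a$gas$min15$truth$qs_qt,
    true_shunt_min20 = a$gas$min20$truth$qs_qt,
    true_airspace_frac = a$histology$truth$fractions[["airspace"]],
    exvivo_weight_g = a$necropsy$exvivo_weight_g,
    body_kg = a$necropsy$body_kg)
}))
write.csv(truths, file.path(RESULTS_DIR, "cohort_truth.csv"), row.names = FALSE)

message(sprintf("Simulated %d animals (seed %d): severity %s",
                N_ANIMALS, COHORT_SEED,
                paste(round(truths$severity, 2), collapse = ", ")))
message(sprintf("True post-CPR lung weight spans %.0f-%.0f g (baseline %.0f-%.0f g)",
                min(truths$true_weight_post_g), max(truths$true_weight_post_g),
                min(truths$true_weight_base_g), max(truths$true_weight_base_g)))
message("Wrote results/cohort_truth.csv")
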