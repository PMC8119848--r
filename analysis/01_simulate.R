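#!/usr/bin/env Rscript
# Simulate the study cohort: 11 controls and 14 stroke survivors with the
# planted effect structure (10-20 Hz power and connectivity deficits, 15-50 Hz
# left-hemisphere power loss, 35-40 Hz connectivity gain in the stroke group).
# Desk scale: 40-s recordings at 200 Hz on a 19-channel montage with 6 regions;
# a real study would use ~180 s at 1 kHz on 64 channels.
#
# Writes results/cohort/: one internal-container recording and one ground-truth
# JSON per subject, plus the cohort manifest.

library(restnet)

seed <- 20210323
out_dir <- file.path("results", "cohort")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

montage <- standard_montage(19)
effects <- cohort_effects(n_regions = 6, snr = 2)
cohort <- simulate_cohort(n_control = 11, n_stroke = 14, effects = effects,
                          montage = montage, duration = 40, fs = 200,
                          seed = seed)

# upper-extremity motor scores for the stroke subjects (clinical inputs of the
# analysis; controls are unimpaired)
fma_motor <- c(63, 62, 29, 28, 61, 51, 31, 38, 34, 23, 21, 21, 30, 27)

manifest <- data.frame(subject = character(0), group = character(0),
                       fma = numeric(0), file = character(0))
k_stroke <- 0
for (s in seq_along(cohort)) {
  rec <- cohort[[s]]$recording
  if (rec$group == "stroke") {
    k_stroke <- k_stroke + 1
    rec$fma <- fma_motor[k_stroke]
  }
  f <- file.path(out_dir, paste0(rec$subject_id, ".rds"))
  write_recording(rec, f)
  write_ground_truth(cohort[[s]]$truth,
                     file.path(out_dir, paste0(rec$subject_id, "_truth.json")))
  manifest <- rbind(manifest, data.frame(subject = rec$subject_id,
                                         group = rec$group, fma = rec$fma,
                                         file = f))
}
saveRDS(pseudo_inverse(cohort[[1]]$truth$mixing),
        file.path(out_dir, "inverse_operator.rds"))
write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d recordings (%d control, %d stroke), seed %d.\n",
            nrow(manifest), sum(manifest$group == "control"),
            sum(manifest$group == "stroke"), seed))
cat(sprintf("Planted: stroke source power x%.2f in 10-20 Hz; left-hemisphere
amplitude x%.2f in 15-50 Hz; planted edge envelope correlation %.2f (controls,
all bands) vs %.2f (stroke, 10-20 Hz) and %.2f (stroke, 35-40 Hz).\n",
            effects$power_deficit^2, effects$asym_factor, effects$conn_rho,
            effects$conn_deficit_rho, effects$conn_gain_rho))
cat("Artifacts under", out_dir, "\n")
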