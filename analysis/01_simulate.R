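#!/usr/bin/env Rscript
# Simulate a cohort with the statistical structure of the combined
# thalamic-LFP + EEG study and serialise it through the on-disk formats
# the later steps read back: Percept-style BrainSense JSON per patient
# (bipolar LFP), a BrainVision triplet (EEG + markers), an event CSV and
# the clinical score table. Sizes are the package's scaled study
# emulation: 6 patients, 120 s per session, a 10-channel montage on the
# 250 Hz LFP time base (see the methods vignette).

suppressPackageStartupMessages(library(thalcortex))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- generate_cohort(
  n_patients = 6, kappa_range = c(2, 30), seed = seed, duration = 120,
  channels = c("Fz", "F1", "F2", "FC1", "FC2",
               "Cz", "Pz", "Oz", "C3", "C4"),
  n_tics = 8, ramp_start = -0.3, ramp_depth = 0.8, eeg_rate = 250)

for (p in cohort$patients) {
  stem <- file.path(out, p$id)
  write_percept_json(p$lfp, paste0(stem, "_lfp.json"))
  write_brainvision(p$eeg, p$events, paste0(stem, "_eeg"))
  utils::write.csv(as.data.frame(p$events), paste0(stem, "_events.csv"),
                   row.names = FALSE)
}
utils::write.csv(cohort$clinical, file.path(out, "clinical.csv"),
                 row.names = FALSE)
truth <- ground_truth_report(cohort)
utils::write.csv(truth, file.path(out, "ground_truth.csv"),
                 row.names = FALSE)

cat(sprintf("simulated %d patients (seed %d) into %s\n",
            length(cohort$patients), seed, out))
cat(sprintf("coupled Fz kappa range: %.1f-%.1f (expected PLV %.2f-%.2f)\n",
            min(truth$kappa[truth$channel == "Fz"]),
            max(truth$kappa[truth$channel == "Fz"]),
            min(truth$expected_plv[truth$channel == "Fz"]),
            max(truth$expected_plv[truth$channel == "Fz"])))
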