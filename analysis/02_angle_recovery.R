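#!/usr/bin/env Rscript
# Recovery of the vertical-vortex-core (VVC) angle from synthetic LV
# acquisitions: phantoms embed a Lamb-Oseen vortex tube at known polar
# angles {0, 10, 20, 30} degrees (five noise seeds each); the full pipeline
# (Lambda2 extraction, component classification, centerline fit, angle
# against the anatomical centerline) must recover the tilt. Writes
# results/angle_recovery.csv.

suppressPackageStartupMessages(library(lvflow))

cases <- expand.grid(polar_deg = c(0, 10, 20, 30), seed = 1:5)
rows <- lapply(seq_len(nrow(cases)), function(i) {
  polar <- cases$polar_deg[i]; seed <- cases$seed[i]
  ph <- make_lv_phantom(
    phantom_config(seed = seed),
    phantom_truth(vvc_polar_deg = polar, vvc_azimuth_deg = 40 * seed))
  res <- analyze_session(ph$field, ph$magnitude, ph$mask,
                         study_params(unwrap = FALSE))
  data.frame(polar_true_deg = polar, seed = seed,
             angle_recovered_deg = res$metrics$angle_deg,
             azimuth_true_deg = (40 * seed) %% 360,
             azimuth_recovered_deg = res$metrics$orientation_azimuth_deg,
             vvc_phase = res$metrics$vvc_phase)
})
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/angle_recovery.csv", row.names = FALSE)
print(out, digits = 3)
cat(sprintf("\nMean absolute angle error: %.2f deg over %d phantoms (voxelization bias grows mildly with tilt).\n",
            mean(abs(out$angle_recovered_deg - out$polar_true_deg)), nrow(out)))
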