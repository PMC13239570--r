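#!/usr/bin/env Rscript
# Bone-suppressed dual-energy image generation: MI registration of each
# HE/LE pair, weighted log subtraction at the domain ws, and a check of
# the calibrated weighting factor against the analytic bone ratio.
# Outputs: results/sequences/example_phantom_de.*, results/de_summary.csv

library(trackrel)

seqdir <- file.path("results", "sequences")
seq_ph <- read_sequence(file.path(seqdir, "example_phantom"))

de <- de_subtract_sequence(seq_ph, wls_config(ws = default_ws("phantom")))
write_sequence(de, file.path(seqdir, "example_phantom_de"))

# calibrate ws from rib vs inter-rib ROIs on a noiseless render
phantom <- phantom_spec(image_size = c(96L, 96L), tumor_diameter_mm = 10,
                        rib_offset_px = 0L)
acq0 <- acquisition_spec(n_frames = 2, noise_model = "none")
ih <- render_projection(phantom, c(0, 0), "HE", acq0)
il <- render_projection(phantom, c(0, 0), "LE", acq0)
bone_roi <- matrix(FALSE, 96, 96); bone_roi[2:5, 5:15] <- TRUE
ref_roi <- matrix(FALSE, 96, 96); ref_roi[10:14, 5:15] <- TRUE
ws_cal <- calibrate_ws(ih, il, bone_roi, ref_roi)

summary <- data.frame(
  ws_used = de$ws,
  ws_calibrated = ws_cal,
  median_registration_dx = stats::median(de$registration_shift_px[, 1]),
  median_registration_dy = stats::median(de$registration_shift_px[, 2]),
  n_pairs = length(de$frames))
dir.create("results", showWarnings = FALSE)
utils::write.csv(summary, file.path("results", "de_summary.csv"),
                 row.names = FALSE)

cat(sprintf("Subtracted %d HE/LE pairs at ws = %.2f (calibrated ws = %.3f).\n",
            summary$n_pairs, summary$ws_used, summary$ws_calibrated))
cat(sprintf("Median recovered inter-pulse shift: (%d, %d) px.\n",
            summary$median_registration_dx, summary$median_registration_dy))
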