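#!/usr/bin/env Rscript
# Generate example fast-kV-switching fluoroscopy sequences: one thorax
# phantom acquisition (10 mm tumor, slow cos^4 breathing) and one
# irregular patient-like breather, with their programmed trajectories.
# Outputs: results/sequences/*.tif/.json, results/sequences/*_truth.csv

library(trackrel)

out <- file.path("results", "sequences")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
config <- study_config(master_seed = 1L)

acq <- acquisition_spec(n_frames = config$n_frames,
                        inter_pulse_offset_px = config$inter_pulse_offset_px,
                        noise_model = "gaussian",
                        noise_scale = config$phantom_noise_scale)
phantom <- phantom_spec(image_size = config$image_size,
                        tumor_diameter_mm = 10,
                        rib_thickness_mm = config$phantom_rib_thickness_mm,
                        rib_offset_px = config$phantom_rib_offset_px)
seq_ph <- generate_sequence(phantom, config$phantom_motions$slow, acq,
                            seed = split_seed(1L, 1L),
                            dataset_id = "example_phantom")
write_sequence(seq_ph, file.path(out, "example_phantom"))
write_trajectory(phantom_gt(config$phantom_motions$slow, seq_ph$meta$t_s),
                 file.path(out, "example_phantom_truth.csv"))

pat_motion <- motion_spec("irregular", amplitude_mm = 7.5, period_s = 3,
                          amplitude_jitter_frac = 0.25,
                          period_jitter_frac = 0.2,
                          drift_mm_per_s = 0.1, lateral_frac = 0.15,
                          seed = split_seed(1L, 1001L))
pat_phantom <- phantom_spec(image_size = config$image_size,
                            tumor_diameter_mm = 8,
                            rib_thickness_mm = config$patient_rib_thickness_mm,
                            rib_offset_px = config$patient_rib_offset_px)
acq_pat <- acq; acq_pat$noise_scale <- 2.5
seq_pat <- generate_sequence(pat_phantom, pat_motion, acq_pat,
                             seed = split_seed(1L, 2L),
                             dataset_id = "example_patient",
                             domain = "patient")
write_sequence(seq_pat, file.path(out, "example_patient"))

cat(sprintf(
  "Wrote %d-frame phantom and patient-like sequences (%dx%d px, %g fps pulses).\n",
  config$n_frames, config$image_size[1], config$image_size[2],
  acq$frame_rate_fps))
cat(sprintf("Phantom SI excursion: %.1f mm peak-to-peak (cos^4, T = %g s).\n",
            diff(range(seq_ph$true_trajectory$y_mm)),
            config$phantom_motions$slow$period_s))
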