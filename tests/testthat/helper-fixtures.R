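# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# miniature end-to-end study (one per suite; ~10 s)
fixture_study <- function() {
  if (is.null(.fixture_cache$study))
    .fixture_cache$study <- suppressWarnings(run_study(make_fixtures(seed = 1L)))
  .fixture_cache$study
}

# small noiseless phantom sequence + template
fixture_sequence <- function(noise = "none", noise_scale = 1, seed = 7L,
                             tumor_mm = 10, n_frames = 12L,
                             offset = c(0L, 0L), rib_mm = 8) {
  ph <- phantom_spec(image_size = c(64L, 64L), tumor_diameter_mm = tumor_mm,
                     rib_thickness_mm = rib_mm)
  acq <- acquisition_spec(n_frames = n_frames, noise_model = noise,
                          noise_scale = noise_scale,
                          inter_pulse_offset_px = offset)
  seq <- generate_sequence(ph, motion_spec("cos4", 7.5, 5), acq, seed = seed)
  list(phantom = ph, acq = acq, seq = seq,
       template = make_template(ph, acq))
}

as_trajectory <- function(df, source = "programmed") {
  structure(df, class = c("trajectory", "data.frame"), source = source)
}
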