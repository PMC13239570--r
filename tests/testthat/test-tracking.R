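test_that("masked NCC surface matches a brute-force oracle", {
  set.seed(11)
  worst <- 0
  for (k in 1:60) {
    nr <- sample(8:14, 1); nc <- sample(8:14, 1)
    pr <- sample(3:5, 1); pc <- sample(3:5, 1)
    img <- matrix(rnorm(nr * nc), nr, nc)
    patch <- matrix(rnorm(pr * pc), pr, pc)
    mask <- matrix(runif(pr * pc) < 0.8, pr, pc)
    if (sum(mask) < 3) mask[] <- TRUE
    tpl <- list(patch = patch, mask = mask, origin_offset_px = c(0, 0))
    rows <- 1:(nr - pr + 1); cols <- 1:(nc - pc + 1)
    surf <- trackrel:::ncc_surface_cpp(img, patch, mask,
                                       as.integer(rows), as.integer(cols))
    oracle <- brute_ncc(img, patch, mask, rows, cols)
    worst <- max(worst, max(abs(surf - oracle)))
  }
  expect_lt(worst, 1e-10)
})

test_that("NCC self-match and anti-correlation hit the bounds", {
  set.seed(3)
  img <- matrix(rnorm(100), 10, 10)
  patch <- img[4:6, 5:7]
  mask <- matrix(TRUE, 3, 3)
  tpl <- list(patch = patch, mask = mask, origin_offset_px = c(1, 1))
  surf <- ncc_surface(img, tpl, c(6, 5), 3)
  expect_equal(max(surf), 1.0, tolerance = 1e-12)
  pk <- locate_peak(surf)
  expect_equal(attr(surf, "cand_rows")[pk$peak[1]], 5)
  expect_equal(attr(surf, "cand_cols")[pk$peak[2]], 6)

  img2 <- -img
  surf2 <- ncc_surface(img2, tpl, c(6, 5), 3)
  expect_equal(min(surf2), -1.0, tolerance = 1e-12)
  expect_true(all(surf >= -1 - 1e-12 & surf <= 1 + 1e-12))
})

test_that("peak localization matches exhaustive argmax and breaks ties low", {
  set.seed(21)
  for (k in 1:100) {
    surf <- matrix(rnorm(63), 7, 9)
    got <- locate_peak(surf)
    want <- brute_argmax(surf)
    expect_identical(as.integer(got$peak), as.integer(want$peak))
    expect_identical(got$score, want$score)
  }
  twin <- matrix(0, 5, 5); twin[2, 4] <- twin[4, 2] <- 1
  expect_equal(locate_peak(twin)$peak, c(2, 4))
  flat <- matrix(1, 4, 4)
  expect_true(locate_peak(flat)$missing)
})

test_that("PSR behaves like a correlation-filter confidence", {
  # LLN: unit-normal sidelobe, isolated peak p -> PSR converges to p
  set.seed(5)
  side <- matrix(rnorm(101 * 101), 101, 101)
  p <- 12
  side[51, 51] <- p
  got <- psr(side, c(51, 51), exclusion_radius_px = 5)
  expect_equal(as.numeric(got), p, tolerance = 0.05 * p)

  # degenerate sidelobe -> capped and flagged
  flat <- matrix(0.5, 9, 9); flat[5, 5] <- 1
  capped <- psr(flat, c(5, 5), exclusion_radius_px = 1, cap = 99)
  expect_equal(as.numeric(capped), 99)
  expect_true(attr(capped, "capped"))

  # duplicate peak in the sidelobe strictly lowers the PSR
  base <- matrix(0, 9, 9); base[5, 5] <- 1
  set.seed(8); base <- base + matrix(rnorm(81, sd = 0.01), 9, 9)
  dup <- base; dup[1, 9] <- dup[5, 5]
  expect_lt(psr(dup, c(5, 5), 1), psr(base, c(5, 5), 1))
})

test_that("PSR decays as sidelobe noise grows", {
  meds <- vapply(c(0.05, 0.2, 0.8), function(sd) {
    stats::median(vapply(1:50, function(s) {
      set.seed(s)
      surf <- matrix(rnorm(31 * 31, sd = sd), 31, 31)
      surf[16, 16] <- 1
      as.numeric(psr(surf, c(16, 16), 3))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) <= 0))
})

test_that("noiseless overlap-free tracking follows the true trajectory", {
  fx <- fixture_sequence(noise = "none", rib_mm = 0, n_frames = 16L)
  trk <- track_sequence(fx$seq, fx$template,
                        tracking_config(search_half_px = 14), "SE")
  expect_false(any(trk$missing))
  truth <- energy_stream(fx$seq, "HE")$true_trajectory
  err <- sqrt((trk$x_mm - truth$x_mm)^2 + (trk$y_mm - truth$y_mm)^2)
  # sub-pixel truth vs integer peak: within one pixel at isocenter
  expect_lt(max(err), fx$seq$pixel_spacing_mm / (150 / 100) * 1.01)
  expect_equal(attr(trk, "effective_dt_s"), 1 / 7.5)
  expect_equal(attr(trk, "modality"), "SE")
})

test_that("pure-noise frames are marked missing under the score criterion", {
  fx <- fixture_sequence(noise = "none", n_frames = 4L)
  seq <- fx$seq
  set.seed(2)
  seq$frames <- lapply(seq$frames, function(f)
    matrix(rnorm(length(f), 1000, 50), nrow(f), ncol(f)))
  trk <- track_sequence(seq, fx$template,
                        tracking_config(search_half_px = 10,
                                        min_score = 0.5), "SE")
  expect_true(all(trk$missing))
})

test_that("tracking is translation-equivariant", {
  fx <- fixture_sequence(noise = "none", rib_mm = 0, n_frames = 2L)
  img <- fx$seq$frames[[1]]
  s0 <- locate_peak(ncc_surface(img, fx$template, c(32, 32), 12))
  sh <- trackrel:::shift_image(img, c(3, -2))
  s1 <- locate_peak(ncc_surface(sh, fx$template, c(32, 32), 12))
  expect_equal(s1$peak - s0$peak, c(-2, 3))  # (row, col) = (dy, dx)
})

test_that("bone overlap degrades SE confidence more than DE", {
  # small tumor dwelling in an inter-rib gap: overlap only on excursion
  ph <- phantom_spec(image_size = c(96L, 96L), tumor_diameter_mm = 5,
                     rib_offset_px = 5L, rib_thickness_mm = 20)
  acq <- acquisition_spec(n_frames = 80L, noise_model = "gaussian",
                          noise_scale = 1, inter_pulse_offset_px = c(1L, 1L))
  seq <- generate_sequence(ph, motion_spec("cos4", 7.5, 5), acq, seed = 9)
  tpl <- make_template(ph, acq)
  de <- de_subtract_sequence(seq, wls_config(ws = 0.69))
  cfg <- tracking_config(search_half_px = 16)
  trk_se <- track_sequence(seq, tpl, cfg, "SE")
  trk_de <- track_sequence(de, tpl, cfg, "DE")

  r_px <- 2.5 * magnification(acq) / ph$pixel_spacing_mm
  overlap_frac <- function(y_mm) {
    ctr <- ph$tumor_center_px[2] + y_mm * magnification(acq)
    rows <- round(ctr - r_px):round(ctr + r_px)
    mean(((rows - 1 - ph$rib_offset_px) %% ph$rib_period_px) <
           ph$rib_width_px)
  }
  split_scores <- function(trk, truth) {
    ov <- vapply(truth$y_mm, overlap_frac, numeric(1)) > 0.3
    list(over = trk$match_score[ov & !trk$missing],
         free = trk$match_score[!ov & !trk$missing],
         over_psr = trk$psr[ov & !trk$missing],
         free_psr = trk$psr[!ov & !trk$missing])
  }
  se <- split_scores(trk_se, energy_stream(seq, "HE")$true_trajectory)
  de_s <- split_scores(trk_de, de$true_trajectory)
  expect_gt(length(se$over), 5); expect_gt(length(se$free), 5)
  expect_lt(stats::median(se$over), stats::median(se$free))
  expect_lt(stats::median(se$over_psr), stats::median(se$free_psr))
  se_drop <- stats::median(se$free) - stats::median(se$over)
  de_drop <- stats::median(de_s$free) - stats::median(de_s$over)
  expect_lt(de_drop, se_drop)
})
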