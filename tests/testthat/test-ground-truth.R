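test_that("programmed ground truth shares the generator's code path", {
  m <- motion_spec("cos4", 7.5, 5)
  t <- seq(0, 10, by = 1 / 7.5)
  gt <- phantom_gt(m, t)
  expect_equal(gt$y_mm, lujan_trajectory(m, t), tolerance = 1e-12)
  expect_true(all(phantom_gt(motion_spec("stationary"), t)$y_mm == 0))

  path <- tempfile(fileext = ".csv")
  write_trajectory(gt, path)
  back <- read_trajectory(path)
  expect_equal(back$y_mm, gt$y_mm, tolerance = 1e-9)
  expect_equal(attr(back, "source"), "programmed")
})

test_that("constant-acceleration Kalman filter nails exact linear motion", {
  dt <- 1 / 7.5
  n <- 120
  t <- (0:(n - 1)) * dt
  # constant position, tiny r: output follows measurements immediately
  meas <- cbind(rep(2, n), rep(-1, n))
  egt <- kalman_egt(meas, dt, kalman_config(measurement_noise_r = 1e-10))
  expect_equal(egt$x_mm[-1], rep(2, n - 1), tolerance = 1e-6)

  # noiseless constant velocity: post-convergence error < 1e-6 mm
  meas2 <- cbind(0.5 * t, 3 * t)
  egt2 <- kalman_egt(meas2, dt, kalman_config(measurement_noise_r = 1e-9,
                                              process_noise_q = 1))
  tail_idx <- (n - 20):n
  expect_lt(max(abs(egt2$y_mm[tail_idx] - 3 * t[tail_idx])), 1e-6)
})

test_that("Kalman eGT denoises a cos^4 trajectory below the noise floor", {
  dt <- 1 / 7.5
  t <- seq(0, 30, by = dt)
  truth <- lujan_trajectory(motion_spec("cos4", 7.5, 5), t)
  rmse <- vapply(1:20, function(s) {
    set.seed(s)
    meas <- cbind(rnorm(length(t), 0, 1), truth + rnorm(length(t), 0, 1))
    egt <- kalman_egt(meas, dt)
    sqrt(mean((egt$y_mm - truth)^2))
  }, numeric(1))
  expect_lt(mean(rmse), 1)
})

test_that("missing frames are bridged by prediction and inputs validated", {
  dt <- 0.2; n <- 50
  t <- (0:(n - 1)) * dt
  y <- 2 * t
  meas <- cbind(rep(0, n), y)
  meas[20:24, ] <- NA
  egt <- kalman_egt(meas, dt, kalman_config(measurement_noise_r = 1e-6,
                                            process_noise_q = 1))
  expect_false(anyNA(egt$y_mm))
  expect_lt(max(abs(egt$y_mm[20:24] - y[20:24])), 0.05)
  expect_error(kalman_egt(matrix(NA_real_, 10, 2), dt), "non-missing")
  expect_error(kalman_egt(meas[1:2, ], dt), "non-missing")
})

test_that("raising process noise moves the filter toward the measurements", {
  dt <- 1 / 7.5
  t <- seq(0, 20, by = dt)
  set.seed(4)
  meas <- cbind(rnorm(length(t)), lujan_trajectory(motion_spec("cos4"), t) +
                  rnorm(length(t)))
  dev <- vapply(c(10, 150, 2000), function(q) {
    egt <- kalman_egt(meas, dt, kalman_config(process_noise_q = q))
    mean(abs(egt$y_mm - meas[, 2]))
  }, numeric(1))
  expect_true(all(diff(dev) <= 0))
})

test_that("eGT outlier flagging isolates injected jumps", {
  dt <- 1 / 7.5
  t <- (0:99) * dt
  truth <- lujan_trajectory(motion_spec("cos4", 7.5, 5), t)
  meas <- cbind(rep(0, 100), truth)
  egt <- kalman_egt(meas, dt, kalman_config(measurement_noise_r = 1e-8))
  expect_length(flag_egt_outliers(egt, meas, 4), 0)

  meas2 <- meas; meas2[60, 2] <- meas2[60, 2] + 15
  egt2 <- kalman_egt(meas, dt, kalman_config(measurement_noise_r = 1e-8))
  expect_identical(flag_egt_outliers(egt2, meas2, 4), 60L)
  expect_length(flag_egt_outliers(egt2, meas2, Inf), 0)
})

test_that("TSR counts strictly sub-threshold errors over tracked frames", {
  trk <- structure(data.frame(
    frame_index = 1:10, t_s = (0:9) / 7.5,
    x_mm = 0, y_mm = c(rep(0, 5), rep(3, 5)),
    match_score = 0.9, psr = 5, missing = FALSE),
    class = c("track_series", "data.frame"))
  ref <- as_trajectory(data.frame(index = 1:10, t_s = (0:9) / 7.5,
                                  x_mm = 0, y_mm = 0))
  r <- tsr(trk, ref)
  expect_equal(r$tsr, 50)
  expect_equal(r$n_missing, 0)

  trk$y_mm[1:5] <- 2.0  # boundary: strict < 2 mm
  expect_equal(tsr(trk, ref)$tsr, 0)

  trk2 <- trk; trk2$y_mm <- 0
  trk2$missing[1:4] <- TRUE
  r2 <- tsr(trk2, ref)
  expect_equal(r2$n_missing, 4)
  expect_equal(r2$n_tracked, 6)
  expect_equal(r2$tsr, 100)

  trk3 <- trk; trk3$missing <- TRUE
  expect_error(tsr(trk3, ref), "undefined")

  # monotone non-decreasing in the threshold
  set.seed(6)
  trk4 <- trk; trk4$y_mm <- runif(10, 0, 5); trk4$missing <- FALSE
  tsrs <- vapply(c(0.5, 1, 2, 4, 6), function(th)
    tsr(trk4, ref, th)$tsr, numeric(1))
  expect_true(all(diff(tsrs) >= 0))
  expect_true(all(tsrs >= 0 & tsrs <= 100))
})

test_that("size-baseline midpoints reproduce the stratification thresholds", {
  expect_equal(unname(quality_midpoints(c(47.6, 72.2, 84.2))),
               c(59.9, 78.2))
  expect_equal(unname(quality_midpoints(c(0, 100, 100))), c(50, 100))
  expect_equal(unname(quality_midpoints(c(70, 70, 70))), c(70, 70))
  expect_error(quality_midpoints(c(1, 2)), "three")
})

test_that("stratification uses closed/open band boundaries", {
  b <- quality_bands()
  expect_equal(stratify(47.6, b), "poor")
  expect_equal(stratify(59.5, b), "moderate")   # inclusive lower bound
  expect_equal(stratify(78.0, b), "moderate")   # inclusive upper bound
  expect_equal(stratify(78.01, b), "good")
  expect_equal(stratify(84.2, b), "good")
  expect_error(quality_bands(poor_upper = 80, good_lower = 60))

  # baselines fall into their own bands under the midpoint thresholds
  mids <- quality_midpoints(c(47.6, 72.2, 84.2))
  bm <- quality_bands(poor_upper = mids[1], good_lower = mids[2])
  expect_equal(vapply(c(47.6, 72.2, 84.2), stratify, character(1), bm),
               c("poor", "moderate", "good"))
})
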