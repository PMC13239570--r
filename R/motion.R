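#' Breathing motion specification
#'
#' Describes the superior-inferior tumor motion programmed into a
#' synthetic acquisition: an even-power (cos^4) breathing waveform, an
#' irregular "patient-like" variant with cycle-to-cycle amplitude and
#' period jitter plus baseline drift, or no motion at all.
#'
#' @param waveform one of `"cos4"`, `"irregular"`, `"stationary"`.
#' @param amplitude_mm peak-to-peak displacement in mm at isocenter.
#' @param period_s breathing period in seconds (ignored for stationary).
#' @param phase_s temporal phase offset in seconds.
#' @param amplitude_jitter_frac fractional sd of per-cycle amplitude
#'   (irregular waveform only), in `[0, 1)`.
#' @param period_jitter_frac fractional sd of per-cycle period
#'   (irregular waveform only), in `[0, 1)`.
#' @param drift_mm_per_s linear baseline drift velocity in mm/s.
#' @param lateral_frac fraction of the SI displacement also applied
#'   along the lateral (x) image axis, for test variety.
#' @param seed integer seed driving the irregular waveform.
#'
#' @return an object of class `motion_spec`.
#' @export
motion_spec <- function(waveform = c("cos4", "irregular", "stationary"),
                        amplitude_mm = 7.5, period_s = 5, phase_s = 0,
                        amplitude_jitter_frac = 0, period_jitter_frac = 0,
                        drift_mm_per_s = 0, lateral_frac = 0, seed = 1L) {
  waveform <- match.arg(waveform)
  if (amplitude_mm < 0) stop("amplitude_mm must be >= 0")
  if (waveform != "stationary" && period_s <= 0)
    stop("period_s must be > 0 for a non-stationary waveform")
  if (amplitude_jitter_frac < 0 || amplitude_jitter_frac >= 1 ||
      period_jitter_frac < 0 || period_jitter_frac >= 1)
    stop("jitter fractions must lie in [0, 1)")
  structure(list(
    waveform = waveform, amplitude_mm = amplitude_mm, period_s = period_s,
    phase_s = phase_s, amplitude_jitter_frac = amplitude_jitter_frac,
    period_jitter_frac = period_jitter_frac,
    drift_mm_per_s = drift_mm_per_s, lateral_frac = lateral_frac,
    seed = as.integer(seed)
  ), class = "motion_spec")
}

#' Even-power (cos^4) breathing trajectory
#'
#' Superior-inferior displacement z(t) = A * cos^4(pi * (t - phase) / T),
#' the standard even-power model of quiet breathing: long dwell near
#' exhale, brief excursion to inhale. Displacements lie in `[0, A]` with
#' A the peak-to-peak amplitude.
#'
#' @param motion a [motion_spec()]; `stationary` yields all zeros.
#' @param timestamps numeric vector of times in seconds.
#'
#' @return numeric vector of displacements (mm).
#' @export
lujan_trajectory <- function(motion, timestamps) {
  stopifnot(inherits(motion, "motion_spec"))
  if (motion$waveform == "stationary") return(rep(0, length(timestamps)))
  if (motion$period_s <= 0) stop("period_s must be > 0")
  motion$amplitude_mm *
    cos(pi * (timestamps - motion$phase_s) / motion$period_s)^4
}

#' Irregular patient-like breathing trajectory
#'
#' Cycle-by-cycle perturbation of the cos^4 model: each cycle draws its
#' own amplitude `A * (1 + eps_A)` and period `T * (1 + eps_T)` from
#' Gaussian jitter, and a linear baseline drift is superimposed. With
#' all jitter and drift zero this reduces exactly to
#' [lujan_trajectory()]. Deterministic given the spec's seed.
#'
#' @inheritParams lujan_trajectory
#' @return numeric vector of displacements (mm).
#' @export
irregular_trajectory <- function(motion, timestamps) {
  stopifnot(inherits(motion, "motion_spec"))
  if (motion$waveform == "stationary") return(rep(0, length(timestamps)))
  if (motion$period_s <= 0) stop("period_s must be > 0")
  if (motion$amplitude_jitter_frac == 0 && motion$period_jitter_frac == 0 &&
      motion$drift_mm_per_s == 0)
    return(lujan_trajectory(motion, timestamps))

  t_rel <- timestamps - motion$phase_s
  t_end <- max(t_rel, 0)
  rng <- local_rng(motion$seed)
  # lay out jittered cycles covering [min(t), max(t)]
  t0 <- min(t_rel, 0)
  # walk backwards to cover negative times with the nominal period
  n_back <- ceiling(max(0, -t0) / motion$period_s) + 1L
  starts <- -n_back * motion$period_s
  bounds <- starts
  amps <- numeric(0)
  while (bounds[length(bounds)] < t_end) {
    period <- motion$period_s *
      (1 + motion$period_jitter_frac * rng$norm(1))
    period <- max(period, 0.1 * motion$period_s)
    amp <- motion$amplitude_mm *
      (1 + motion$amplitude_jitter_frac * rng$norm(1))
    amp <- max(amp, 0)
    bounds <- c(bounds, bounds[length(bounds)] + period)
    amps <- c(amps, amp)
  }
  idx <- findInterval(t_rel, bounds, rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), length(amps))
  cyc_start <- bounds[idx]
  cyc_len <- bounds[idx + 1L] - cyc_start
  frac <- (t_rel - cyc_start) / cyc_len
  amps[idx] * cos(pi * frac)^4 + motion$drift_mm_per_s * timestamps
}

#' Evaluate a motion spec at given timestamps
#'
#' Dispatches to the waveform named in the spec.
#' @inheritParams lujan_trajectory
#' @return numeric vector of SI displacements (mm).
#' @export
motion_trajectory <- function(motion, timestamps) {
  switch(motion$waveform,
    stationary = rep(0, length(timestamps)),
    cos4 = lujan_trajectory(motion, timestamps),
    irregular = irregular_trajectory(motion, timestamps)
  )
}

# Self-contained RNG stream that never disturbs the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    norm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    unif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    pois = function(lambda) draw(stats::rpois, length(lambda), lambda),
    int = function(n, max) draw(function(n, max) sample.int(max, n, replace = TRUE), n, max)
  )
}
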