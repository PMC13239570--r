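#' Dual-energy subtraction configuration
#'
#' @param ws weighting factor of the weighted logarithmic subtraction;
#'   the study values are 0.69 for phantom and 0.42 for patient images
#'   (see [default_ws()]).
#' @param max_shift_px half-width of the integer translation search for
#'   the mutual-information registration.
#' @param mi_bins histogram bin count for the mutual information.
#' @param register logical; register each HE/LE pair before subtracting.
#' @return object of class `wls_config`.
#' @export
wls_config <- function(ws = 0.69, max_shift_px = 5L, mi_bins = 32L,
                       register = TRUE) {
  if (ws < 0) stop("ws must be >= 0")
  if (max_shift_px < 0) stop("max_shift_px must be >= 0")
  structure(list(ws = ws, max_shift_px = as.integer(max_shift_px),
                 mi_bins = as.integer(mi_bins), register = register),
            class = "wls_config")
}

#' Study default weighting factor by domain
#' @param domain `"phantom"` or `"patient"`.
#' @return scalar ws (0.69 phantom, 0.42 patient).
#' @export
default_ws <- function(domain = c("phantom", "patient")) {
  switch(match.arg(domain), phantom = 0.69, patient = 0.42)
}

# Shannon mutual information (nats) of two equal-length samples
mutual_information <- function(a, b, bins) {
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2]) return(NA_real_)
  ia <- pmin(as.integer((a - ra[1]) / (ra[2] - ra[1]) * bins) + 1L, bins)
  ib <- pmin(as.integer((b - rb[1]) / (rb[2] - rb[1]) * bins) + 1L, bins)
  joint <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins) / length(a)
  pa <- tabulate(ia, nbins = bins) / length(a)
  pb <- tabulate(ib, nbins = bins) / length(b)
  nz <- joint > 0
  outer_p <- as.vector(outer(pa, pb))
  sum(joint[nz] * log(joint[nz] / outer_p[nz]))
}

#' Register an HE/LE pair by mutual information
#'
#' Exhaustive search over integer translations within
#' `config$max_shift_px` for the shift of the LE image relative to the
#' HE image that maximizes the mutual information of the overlapping
#' region (translation-only rigid model). Ties break toward the
#' smaller shift magnitude, then row, then column.
#'
#' @param ih,il HE and LE intensity matrices of the same shape.
#' @param config a [wls_config()].
#' @return integer `c(dx, dy)`: the estimated translation of `il`
#'   relative to `ih` (apply the negated shift to `il` to align it).
#'   Attribute `low_confidence` is `TRUE` for degenerate (constant or
#'   non-informative) inputs, for which `c(0, 0)` is returned.
#' @export
register_pair <- function(ih, il, config = wls_config()) {
  if (!all(dim(ih) == dim(il))) stop("ih and il must have the same shape")
  m <- config$max_shift_px
  if (m == 0L || stats::sd(ih) == 0 || stats::sd(il) == 0) {
    out <- c(0L, 0L)
    attr(out, "low_confidence") <- TRUE
    return(out)
  }
  nr <- nrow(ih); nc <- ncol(ih)
  best <- -Inf; best_shift <- c(0L, 0L); any_valid <- FALSE
  all_mi <- c()
  for (dy in -m:m) for (dx in -m:m) {
    # il[y, x] ~ ih[y - dy, x - dx]: overlap indices
    r_ih <- max(1, 1 - dy):min(nr, nr - dy)
    c_ih <- max(1, 1 - dx):min(nc, nc - dx)
    a <- ih[r_ih, c_ih]
    b <- il[r_ih + dy, c_ih + dx]
    mi <- mutual_information(as.vector(a), as.vector(b), config$mi_bins)
    if (is.na(mi)) next
    all_mi <- c(all_mi, mi)
    any_valid <- TRUE
    better <- mi > best + 1e-12 ||
      (abs(mi - best) <= 1e-12 && tie_break_shift(c(dx, dy), best_shift))
    if (better) { best <- mi; best_shift <- c(dx, dy) }
  }
  out <- as.integer(best_shift)
  # weak MI peak (e.g. a pure-noise pair) carries no registration signal
  attr(out, "low_confidence") <- !any_valid ||
    best - stats::median(all_mi) < 0.1
  out
}

# prefer smaller |shift|, then smaller dy, then dx
tie_break_shift <- function(cand, cur) {
  n1 <- sum(cand^2); n2 <- sum(cur^2)
  if (n1 != n2) return(n1 < n2)
  if (cand[2] != cur[2]) return(cand[2] < cur[2])
  cand[1] < cur[1]
}

#' Weighted logarithmic subtraction
#'
#' `DE = ln(I_H) - ws * ln(I_L)` per pixel, intensities clamped to
#' `eps` before the log. The result is the raw (pre-rescale) DE image;
#' sequence-level min-max rescaling is applied by
#' [de_subtract_sequence()].
#'
#' @param ih,il registered HE and LE intensity matrices.
#' @param ws weighting factor.
#' @param eps positive clamp applied before the logarithm.
#' @return numeric matrix.
#' @export
wls_subtract <- function(ih, il, ws, eps = 1e-6) {
  if (!all(dim(ih) == dim(il))) stop("ih and il must have the same shape")
  log(pmax(ih, eps)) - ws * log(pmax(il, eps))
}

#' Calibrate the bone-cancelling weighting factor
#'
#' Finds the `ws` that nulls the mean DE contrast between a bone ROI
#' and a bone-free reference ROI: since the DE contrast is
#' `Delta_H - ws * Delta_L` in mean log intensities, the minimizer is
#' their ratio, which equals the bone attenuation ratio
#' `mu_bone(HE) / mu_bone(LE)` on noiseless synthetic input.
#'
#' @param ih,il HE and LE intensity matrices (registered).
#' @param bone_roi,reference_roi logical masks or index sets selecting
#'   the bone-containing and bone-free regions.
#' @param eps clamp before the logarithm.
#' @return scalar ws estimate.
#' @export
calibrate_ws <- function(ih, il, bone_roi, reference_roi, eps = 1e-6) {
  if (!any(bone_roi) || !any(reference_roi)) stop("ROIs must be non-empty")
  lh <- log(pmax(ih, eps)); ll <- log(pmax(il, eps))
  dh <- mean(lh[bone_roi]) - mean(lh[reference_roi])
  dl <- mean(ll[bone_roi]) - mean(ll[reference_roi])
  if (abs(dl) < 1e-12) stop("no bone contrast in the LE image within bone_roi")
  dh / dl
}

#' Bone-suppressed DE sequence from an alternating HE/LE sequence
#'
#' Pairs consecutive HE/LE pulses, optionally registers each pair by
#' mutual information, applies the weighted logarithmic subtraction,
#' and min-max rescales the whole DE sequence to `[0, 1]` using global
#' sequence statistics so template and search frames share one scale.
#' DE frames carry the HE pulse's timestamp (effective rate = half the
#' pulse rate).
#'
#' @param seq an `image_sequence` with strictly alternating HE/LE.
#' @param config a [wls_config()]; `config$ws = NULL` selects the
#'   domain default via [default_ws()].
#' @param i0 incident intensity used to set the log clamp
#'   (`eps = 1e-6 * i0`).
#' @return an `image_sequence` of DE frames with a `rescale` record
#'   (offset, scale) and per-pair `registration_shift_px` metadata.
#' @export
de_subtract_sequence <- function(seq, config = wls_config(), i0 = NULL) {
  en <- seq$meta$energy
  n <- length(seq$frames)
  if (n < 2 || any(en[seq(1, n, 2)] != "HE") ||
      any(en[seq(2, n, 2)] != "LE"))
    stop("sequence must strictly alternate HE/LE starting with HE")
  ws <- if (is.null(config$ws)) default_ws(seq$domain) else config$ws
  if (is.null(i0)) i0 <- max(vapply(seq$frames, max, numeric(1)))
  eps <- 1e-6 * i0
  npair <- n %/% 2
  frames <- vector("list", npair)
  shifts <- matrix(0L, npair, 2)
  for (k in seq_len(npair)) {
    ih <- seq$frames[[2 * k - 1]]
    il <- seq$frames[[2 * k]]
    if (config$register) {
      s <- register_pair(ih, il, config)
      if (any(s != 0L)) il <- shift_image(il, -s)
      shifts[k, ] <- s
    }
    frames[[k]] <- wls_subtract(ih, il, ws, eps)
  }
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(frames, function(f) (f - lo) / scale)
  he_idx <- seq(1, n, 2)
  out <- seq
  out$frames <- frames
  out$meta <- data.frame(index = seq_len(npair),
                         t_s = seq$meta$t_s[he_idx],
                         energy = "DE", stringsAsFactors = FALSE)
  out$true_trajectory <- seq$true_trajectory[he_idx, , drop = FALSE]
  out$true_trajectory$index <- seq_len(npair)
  out$rescale <- list(offset = lo, scale = scale)
  out$registration_shift_px <- shifts
  out$ws <- ws
  out
}
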