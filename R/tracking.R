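#' Tracking configuration
#'
#' @param search_half_px half-width of the square search window around
#'   the previous tracked position (first frame: the image center).
#' @param min_score frames whose NCC peak value falls below this are
#'   marked missing.
#' @param exclusion_radius_px half-width of the square excluded around
#'   the peak when computing the peak-to-sidelobe ratio (default 5,
#'   i.e. an 11x11 exclusion window).
#' @param psr_cap PSR value reported when the sidelobe is degenerate
#'   (zero spread).
#' @param subpixel logical; parabolic subpixel refinement of the peak.
#' @param boundary_missing logical; mark frames whose peak lies on the
#'   search-window boundary as missing.
#' @return object of class `tracking_config`.
#' @export
tracking_config <- function(search_half_px = 20L, min_score = 0.3,
                            exclusion_radius_px = 5L, psr_cap = 100,
                            subpixel = FALSE, boundary_missing = TRUE) {
  structure(list(search_half_px = as.integer(search_half_px),
                 min_score = min_score,
                 exclusion_radius_px = as.integer(exclusion_radius_px),
                 psr_cap = psr_cap, subpixel = subpixel,
                 boundary_missing = boundary_missing),
            class = "tracking_config")
}

#' Tumor template from a noiseless reference render
#'
#' The synthetic analog of deriving the template from the contoured
#' tumor on the planning CT: a noiseless Beer-Lambert render of the
#' tumor alone on a small canvas, with the contour mask given by the
#' tumor's projected support. NCC is masked, so background outside the
#' contour is ignored and the template matches both raw (SE) and
#' subtracted (DE) streams, whose tumor contrast is negative in both.
#'
#' @param phantom a [phantom_spec()].
#' @param acq an [acquisition_spec()].
#' @param halo_px background margin around the tumor support.
#' @return list with `patch` (matrix), `mask` (logical matrix) and
#'   `origin_offset_px` (`c(dx, dy)` from the patch's top-left pixel to
#'   the tumor centroid), class `tumor_template`.
#' @export
make_template <- function(phantom, acq, halo_px = 2L) {
  mag <- magnification(acq)
  r_mm <- phantom$tumor_diameter_mm / 2
  r_px <- r_mm * mag / phantom$pixel_spacing_mm
  half <- ceiling(r_px) + as.integer(halo_px)
  size <- 2L * half + 1L
  ctr <- half + 1L
  d_mm <- (seq_len(size) - ctr) * phantom$pixel_spacing_mm / mag
  d2 <- outer(d_mm^2, d_mm^2, `+`)
  thick <- 2 * sqrt(pmax(r_mm^2 - d2, 0))
  patch <- exp(-phantom$mu_tumor[["HE"]] * thick)
  mask <- thick > 0
  structure(list(patch = patch, mask = mask,
                 origin_offset_px = c(ctr - 1, ctr - 1)),
            class = "tumor_template")
}

#' Masked NCC match-score surface
#'
#' Zero-normalized cross-correlation of the masked template against
#' the image over a square grid of candidate tumor-centroid positions
#' centered at `center_px`. Offsets where the image patch is constant
#' under the mask are defined as 0. The candidate grid is clipped so
#' every placement fits inside the image.
#'
#' @param image numeric matrix.
#' @param template a [make_template()] result (or a compatible list).
#' @param center_px `c(x, y)` search-window center (pixels).
#' @param half_px window half-width in pixels.
#' @return matrix of NCC values in `[-1, 1]` with attributes
#'   `cand_rows` and `cand_cols`, the candidate centroid pixel
#'   coordinates of each surface row/column.
#' @export
ncc_surface <- function(image, template, center_px, half_px) {
  pr <- nrow(template$patch); pc <- ncol(template$patch)
  if (pr > nrow(image) || pc > ncol(image))
    stop("template larger than image")
  offx <- template$origin_offset_px[1]; offy <- template$origin_offset_px[2]
  cx <- round(center_px[1]); cy <- round(center_px[2])
  # centroid coordinates for which the patch placement fits
  row_lo <- 1 + offy; row_hi <- nrow(image) - (pr - 1) + offy
  col_lo <- 1 + offx; col_hi <- ncol(image) - (pc - 1) + offx
  cand_rows <- max(row_lo, cy - half_px):min(row_hi, cy + half_px)
  cand_cols <- max(col_lo, cx - half_px):min(col_hi, cx + half_px)
  if (length(cand_rows) < 1 || length(cand_cols) < 1)
    stop("search window does not fit inside the image")
  surf <- ncc_surface_cpp(image, template$patch,
                          template$mask, as.integer(cand_rows - offy),
                          as.integer(cand_cols - offx))
  attr(surf, "cand_rows") <- cand_rows
  attr(surf, "cand_cols") <- cand_cols
  surf
}

#' Locate the match-surface peak
#'
#' Deterministic argmax: ties break toward the smallest row, then the
#' smallest column. An all-equal surface has no defined peak and
#' signals a missing frame. Optional parabolic subpixel refinement
#' fits a 1-D parabola through the peak and its axial neighbours.
#'
#' @param surface numeric matrix (an [ncc_surface()] result).
#' @param subpixel logical.
#' @return list: `peak` `c(row, col)` matrix indices (fractional when
#'   refined), `score` the peak value, `missing` logical.
#' @export
locate_peak <- function(surface, subpixel = FALSE) {
  if (length(surface) == 0) stop("empty surface")
  mx <- max(surface)
  if (mx == min(surface))
    return(list(peak = c(NA_real_, NA_real_), score = NA_real_,
                missing = TRUE))
  idx <- which(surface == mx)
  nr <- nrow(surface)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  o <- order(rows, cols)[1]
  pk <- c(rows[o], cols[o])
  peak <- as.numeric(pk)
  if (subpixel) {
    peak[1] <- pk[1] + parabolic_offset(surface[, pk[2]], pk[1])
    peak[2] <- pk[2] + parabolic_offset(surface[pk[1], ], pk[2])
  }
  list(peak = peak, score = mx, missing = FALSE)
}

# vertex offset in (-0.5, 0.5) of a parabola through (i-1, i, i+1)
parabolic_offset <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(0)
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (abs(denom) < 1e-12) return(0)
  off <- 0.5 * (v[i - 1] - v[i + 1]) / denom
  max(min(off, 0.5), -0.5)
}

#' Peak-to-sidelobe ratio
#'
#' Correlation-filter confidence of a match-surface peak:
#' `(peak - mean(sidelobe)) / sd(sidelobe)`, where the sidelobe is the
#' surface excluding a square of half-width `exclusion_radius_px`
#' around the peak. A degenerate sidelobe (fewer than 2 cells or zero
#' spread) returns the configured cap with attribute `capped = TRUE`.
#'
#' @param surface numeric matrix.
#' @param peak_idx `c(row, col)` integer matrix indices of the peak.
#' @param exclusion_radius_px half-width of the exclusion square.
#' @param cap value reported for a degenerate sidelobe.
#' @return scalar PSR.
#' @export
psr <- function(surface, peak_idx, exclusion_radius_px = 5L, cap = 100) {
  pr <- round(peak_idx[1]); pc <- round(peak_idx[2])
  rows <- abs(row(surface) - pr) <= exclusion_radius_px
  cols <- abs(col(surface) - pc) <= exclusion_radius_px
  side <- surface[!(rows & cols)]
  if (length(side) < 2 || stats::sd(side) == 0) {
    out <- cap
    attr(out, "capped") <- TRUE
    return(out)
  }
  (surface[pr, pc] - mean(side)) / stats::sd(side)
}

#' Track a tumor through an image sequence
#'
#' Template matching per frame: the masked NCC surface is computed in
#' a search window centered on the previous tracked position (first
#' frame: the image center), the peak gives the predicted position and
#' match score, and the PSR quantifies peak sharpness. A frame is
#' missing when the peak is undefined, the match score falls below
#' `config$min_score`, or the peak lies on the search-window boundary.
#' Positions are reported in mm at isocenter relative to the image
#' center (detector mm divided by the magnification).
#'
#' @param seq an `image_sequence`; for `modality = "SE"` the HE pulses
#'   are tracked, for `"DE"` the sequence must already be subtracted
#'   (see [de_subtract_sequence()]).
#' @param template a [make_template()] result.
#' @param config a [tracking_config()].
#' @param modality `"SE"` or `"DE"`.
#' @return a `track_series`: data.frame with columns `frame_index`,
#'   `t_s`, `x_mm`, `y_mm`, `match_score`, `psr`, `missing`, plus
#'   attributes `modality`, `dataset_id`, `effective_dt_s`,
#'   `search_half_px`.
#' @export
track_sequence <- function(seq, template, config = tracking_config(),
                           modality = c("SE", "DE")) {
  modality <- match.arg(modality)
  if (length(seq$frames) == 0) stop("empty sequence")
  if (modality == "SE") {
    if (!"HE" %in% seq$meta$energy)
      stop("no HE frames in sequence; SE tracking uses the HE stream")
    seq <- energy_stream(seq, "HE")
  } else {
    if (!all(seq$meta$energy == "DE"))
      stop("DE tracking requires a subtracted sequence (run de_subtract_sequence first)")
  }
  n <- length(seq$frames)
  nr <- nrow(seq$frames[[1]]); nc <- ncol(seq$frames[[1]])
  center <- c((nc + 1) / 2, (nr + 1) / 2)
  res <- data.frame(frame_index = seq$meta$index, t_s = seq$meta$t_s,
                    x_mm = NA_real_, y_mm = NA_real_,
                    match_score = NA_real_, psr = NA_real_,
                    missing = TRUE)
  for (i in seq_len(n)) {
    surf <- ncc_surface(seq$frames[[i]], template, center,
                        config$search_half_px)
    pk <- locate_peak(surf, subpixel = config$subpixel)
    if (pk$missing) next
    cand_rows <- attr(surf, "cand_rows"); cand_cols <- attr(surf, "cand_cols")
    on_boundary <- round(pk$peak[1]) %in% c(1L, nrow(surf)) ||
      round(pk$peak[2]) %in% c(1L, ncol(surf))
    if (pk$score < config$min_score ||
        (config$boundary_missing && on_boundary)) {
      res$match_score[i] <- pk$score
      next
    }
    row_px <- cand_rows[1] + (pk$peak[1] - 1)
    col_px <- cand_cols[1] + (pk$peak[2] - 1)
    pos_mm <- px_to_mm(c(col_px, row_px), seq)
    res$x_mm[i] <- pos_mm[1]; res$y_mm[i] <- pos_mm[2]
    res$match_score[i] <- pk$score
    res$psr[i] <- as.numeric(psr(surf, round(pk$peak),
                                 config$exclusion_radius_px,
                                 config$psr_cap))
    res$missing[i] <- FALSE
    center <- c(col_px, row_px)
  }
  dt <- if (n > 1) stats::median(diff(seq$meta$t_s)) else NA_real_
  structure(res, class = c("track_series", "data.frame"),
            modality = modality, dataset_id = seq$dataset_id,
            effective_dt_s = dt, search_half_px = config$search_half_px)
}
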