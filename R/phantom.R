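#' Digital thorax phantom specification
#'
#' A 2-D parallel-path phantom: a smooth soft-tissue thickness map with
#' an elliptical chest profile, periodic horizontal ribs and a vertical
#' spine column of bone, and a spherical tumor whose projected position
#' follows the programmed motion. Thickness maps are in mm of material;
#' projections follow Beer-Lambert with per-material, per-energy linear
#' attenuation coefficients.
#'
#' Default attenuation coefficients give a bone HE/LE ratio of 0.69
#' (matching the weighting factor that cancels bone in the dual-energy
#' subtraction) and a tissue LE/HE ratio below the bone LE/HE ratio,
#' the physical condition for dual-energy bone/tissue contrast.
#'
#' @param image_size `c(nrow, ncol)` detector size in pixels.
#' @param pixel_spacing_mm detector pixel pitch (mm).
#' @param tumor_diameter_mm spherical tumor diameter (mm); the study
#'   sizes are 5, 10 and 15 mm but any positive value is accepted.
#' @param tumor_center_px base tumor center `c(x, y)` in pixels
#'   (defaults to the image center).
#' @param mu_tissue,mu_bone,mu_tumor named `c(HE=, LE=)` linear
#'   attenuation coefficients per mm.
#' @param tissue_thickness_mm peak soft-tissue path length (mm).
#' @param rib_period_px,rib_width_px,rib_thickness_mm horizontal rib
#'   band layout; `rib_thickness_mm = 0` removes the ribs.
#' @param rib_offset_px 0-based row offset of the first rib; the
#'   default leaves the image-center rows (the tumor's exhale dwell)
#'   in an inter-rib gap so bone overlap happens on excursion.
#' @param spine_cols columns occupied by the spine (bone), or `NULL`.
#' @param spine_thickness_mm spine bone path length (mm).
#'
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(96L, 96L), pixel_spacing_mm = 1.0,
                         tumor_diameter_mm = 10,
                         tumor_center_px = NULL,
                         mu_tissue = c(HE = 0.0195, LE = 0.022),
                         mu_bone = c(HE = 0.0345, LE = 0.05),
                         mu_tumor = c(HE = 0.027, LE = 0.0304),
                         tissue_thickness_mm = 120,
                         rib_period_px = 16L, rib_width_px = 5L,
                         rib_thickness_mm = 20, rib_offset_px = 5L,
                         spine_cols = NULL, spine_thickness_mm = 20) {
  stopifnot(length(image_size) == 2, all(image_size >= 8),
            pixel_spacing_mm > 0, tumor_diameter_mm > 0)
  mus <- rbind(tissue = mu_tissue, bone = mu_bone, tumor = mu_tumor)
  if (any(mus < 0)) stop("attenuation coefficients must be >= 0")
  if (all(c(mu_bone, mu_tissue) > 0) &&
      mu_bone[["LE"]] / mu_bone[["HE"]] <= mu_tissue[["LE"]] / mu_tissue[["HE"]])
    stop("dual-energy contrast condition violated: need bone LE/HE ratio > tissue LE/HE ratio")
  if (is.null(tumor_center_px))
    tumor_center_px <- c((image_size[2] + 1) / 2, (image_size[1] + 1) / 2)
  structure(list(
    image_size = as.integer(image_size), pixel_spacing_mm = pixel_spacing_mm,
    tumor_diameter_mm = tumor_diameter_mm, tumor_center_px = tumor_center_px,
    mu_tissue = mu_tissue, mu_bone = mu_bone, mu_tumor = mu_tumor,
    tissue_thickness_mm = tissue_thickness_mm,
    rib_period_px = as.integer(rib_period_px),
    rib_width_px = as.integer(rib_width_px),
    rib_thickness_mm = rib_thickness_mm,
    rib_offset_px = as.integer(rib_offset_px),
    spine_cols = spine_cols, spine_thickness_mm = spine_thickness_mm
  ), class = "phantom_spec")
}

#' Acquisition specification
#'
#' Timing, geometry, energies and noise of a fast-kV-switching
#' fluoroscopy run: pulses alternate HE/LE at `frame_rate_fps` so each
#' consecutive pair yields one dual-energy image at half the pulse rate.
#'
#' @param frame_rate_fps pulse rate (default 15, giving 7.5 fps DE).
#' @param n_frames total number of pulses (HE + LE).
#' @param inter_pulse_offset_px `c(dx, dy)` whole-image pixel shift
#'   applied to each LE frame, emulating gantry motion between pulses.
#' @param sdd_cm,sad_cm source-to-detector / source-to-axis distances;
#'   their ratio is the projection magnification.
#' @param noise_model `"none"`, `"gaussian"` (sd = scale * sqrt(counts),
#'   the Poisson approximation) or `"poisson"`.
#' @param noise_scale multiplier on the Gaussian noise sd.
#' @param i0 incident photon intensity (counts at zero attenuation).
#'
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(frame_rate_fps = 15, n_frames = 30L,
                             inter_pulse_offset_px = c(0L, 0L),
                             sdd_cm = 150, sad_cm = 100,
                             noise_model = c("none", "gaussian", "poisson"),
                             noise_scale = 1, i0 = 2e5) {
  noise_model <- match.arg(noise_model)
  if (frame_rate_fps <= 0) stop("frame_rate_fps must be > 0")
  if (!(sdd_cm > sad_cm && sad_cm > 0)) stop("need sdd_cm > sad_cm > 0")
  if (i0 <= 0) stop("i0 must be > 0")
  structure(list(
    frame_rate_fps = frame_rate_fps, n_frames = as.integer(n_frames),
    inter_pulse_offset_px = as.integer(round(inter_pulse_offset_px)),
    sdd_cm = sdd_cm, sad_cm = sad_cm,
    noise_model = noise_model, noise_scale = noise_scale, i0 = i0
  ), class = "acquisition_spec")
}

#' Projection magnification sdd/sad
#' @param acq an [acquisition_spec()].
#' @return scalar magnification.
#' @export
magnification <- function(acq) acq$sdd_cm / acq$sad_cm

# static thickness maps (mm of material), list(tissue=, bone=)
phantom_thickness_maps <- function(phantom) {
  nr <- phantom$image_size[1]; nc <- phantom$image_size[2]
  col_frac <- (seq_len(nc) - (nc + 1) / 2) / (nc / 2)   # [-1, 1]
  chest <- sqrt(pmax(0, 1 - (0.95 * col_frac)^2))       # elliptical profile
  tissue <- matrix(rep(phantom$tissue_thickness_mm * chest, each = nr), nr, nc)
  bone <- matrix(0, nr, nc)
  if (phantom$rib_thickness_mm > 0 && phantom$rib_period_px > 0) {
    rows <- seq_len(nr)
    in_rib <- ((rows - 1L - phantom$rib_offset_px) %%
                 phantom$rib_period_px) < phantom$rib_width_px
    bone[in_rib, ] <- bone[in_rib, ] + phantom$rib_thickness_mm
  }
  if (!is.null(phantom$spine_cols) && phantom$spine_thickness_mm > 0)
    bone[, phantom$spine_cols] <- bone[, phantom$spine_cols] +
      phantom$spine_thickness_mm
  list(tissue = tissue, bone = bone)
}

# spherical tumor path-length map (mm) for a center displaced by
# (dx_mm, dy_mm) at isocenter from the base center
tumor_thickness_map <- function(phantom, displacement_mm, acq) {
  nr <- phantom$image_size[1]; nc <- phantom$image_size[2]
  mag <- magnification(acq)
  ctr_px <- phantom$tumor_center_px +
    displacement_mm * mag / phantom$pixel_spacing_mm
  r_mm <- phantom$tumor_diameter_mm / 2
  r_px <- r_mm * mag / phantom$pixel_spacing_mm
  if (ctr_px[1] < 1 - r_px || ctr_px[1] > nc + r_px ||
      ctr_px[2] < 1 - r_px || ctr_px[2] > nr + r_px)
    stop(sprintf("tumor center (%.1f, %.1f) px outside the field of view",
                 ctr_px[1], ctr_px[2]))
  dx_mm <- (seq_len(nc) - ctr_px[1]) * phantom$pixel_spacing_mm / mag
  dy_mm <- (seq_len(nr) - ctr_px[2]) * phantom$pixel_spacing_mm / mag
  d2 <- outer(dy_mm^2, dx_mm^2, `+`)
  2 * sqrt(pmax(r_mm^2 - d2, 0))
}

#' Render one noiseless-or-noisy projection
#'
#' Beer-Lambert line-integral renderer: pixel value
#' `i0 * exp(-sum_m mu_m(energy) * t_m(pixel))`, with the tumor placed
#' at the given isocenter displacement (scaled by the magnification
#' sdd/sad), then optional photon noise.
#'
#' @param phantom a [phantom_spec()].
#' @param displacement_mm `c(dx, dy)` tumor displacement at isocenter
#'   (mm); y is the superior-inferior (row) axis.
#' @param energy `"HE"` or `"LE"`.
#' @param acq an [acquisition_spec()].
#' @param rng optional RNG stream from `local_rng()`; required when the
#'   acquisition's noise model is not `"none"`.
#'
#' @return numeric matrix of detector intensities.
#' @export
render_projection <- function(phantom, displacement_mm, energy, acq,
                              rng = NULL) {
  stopifnot(energy %in% c("HE", "LE"))
  maps <- phantom_thickness_maps(phantom)
  t_tum <- tumor_thickness_map(phantom, displacement_mm, acq)
  att <- phantom$mu_tissue[[energy]] * maps$tissue +
    phantom$mu_bone[[energy]] * maps$bone +
    phantom$mu_tumor[[energy]] * t_tum
  img <- acq$i0 * exp(-att)
  if (acq$noise_model != "none") {
    if (is.null(rng)) stop("rng required for a noisy render")
    n <- length(img)
    img <- switch(acq$noise_model,
      gaussian = img + acq$noise_scale * sqrt(img) * rng$norm(n),
      poisson = as.numeric(rng$pois(img)))
    img[img < 1e-3] <- 1e-3
    dim(img) <- c(phantom$image_size[1], phantom$image_size[2])
  }
  img
}

# integer whole-image shift with edge replication; shift = c(dx, dy)
shift_image <- function(img, shift) {
  dx <- as.integer(round(shift[1])); dy <- as.integer(round(shift[2]))
  nr <- nrow(img); nc <- ncol(img)
  src_r <- pmin(pmax(seq_len(nr) - dy, 1L), nr)
  src_c <- pmin(pmax(seq_len(nc) - dx, 1L), nc)
  img[src_r, src_c, drop = FALSE]
}

#' Generate a fast-kV-switching image sequence
#'
#' Renders `n_frames` alternating HE/LE pulses at the acquisition frame
#' rate, starting with HE. Each LE frame is rendered at its own (later)
#' timestamp and then shifted by the acquisition's inter-pulse pixel
#' offset, emulating gantry-motion misregistration. The programmed true
#' trajectory is stored alongside the frames.
#'
#' @param phantom a [phantom_spec()].
#' @param motion a [motion_spec()].
#' @param acq an [acquisition_spec()].
#' @param seed integer seed for the noise realization.
#' @param dataset_id identifier string.
#' @param domain `"phantom"` or `"patient"` provenance flag.
#'
#' @return an `image_sequence`: list with `frames` (list of matrices),
#'   `meta` (data.frame: index, t_s, energy), geometry fields, and
#'   `true_trajectory` (data.frame: index, t_s, x_mm, y_mm at
#'   isocenter relative to the image center).
#' @export
generate_sequence <- function(phantom, motion, acq, seed = 1L,
                              dataset_id = "sim", domain = c("phantom", "patient")) {
  domain <- match.arg(domain)
  if (acq$n_frames < 2) stop("n_frames must be >= 2")
  n <- acq$n_frames
  t_s <- (seq_len(n) - 1L) / acq$frame_rate_fps
  energy <- rep(c("HE", "LE"), length.out = n)
  z <- motion_trajectory(motion, t_s)
  x <- motion$lateral_frac * z
  rng <- local_rng(seed)
  base_mm <- tumor_base_mm(phantom, acq)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    img <- render_projection(phantom, c(x[i], z[i]), energy[i], acq, rng)
    if (energy[i] == "LE" && any(acq$inter_pulse_offset_px != 0L))
      img <- shift_image(img, acq$inter_pulse_offset_px)
    frames[[i]] <- img
  }
  traj <- data.frame(index = seq_len(n), t_s = t_s,
                     x_mm = base_mm[1] + x, y_mm = base_mm[2] + z)
  structure(list(
    frames = frames,
    meta = data.frame(index = seq_len(n), t_s = t_s, energy = energy,
                      stringsAsFactors = FALSE),
    pixel_spacing_mm = phantom$pixel_spacing_mm,
    sdd_cm = acq$sdd_cm, sad_cm = acq$sad_cm,
    dataset_id = dataset_id, domain = domain,
    true_trajectory = traj
  ), class = "image_sequence")
}

# base tumor center in isocenter mm relative to the image center
tumor_base_mm <- function(phantom, acq) {
  ctr <- c((phantom$image_size[2] + 1) / 2, (phantom$image_size[1] + 1) / 2)
  (phantom$tumor_center_px - ctr) * phantom$pixel_spacing_mm / magnification(acq)
}

# px (1-based, c(x, y)) -> isocenter mm relative to image center
px_to_mm <- function(pos_px, seq) {
  ctr <- c((ncol(seq$frames[[1]]) + 1) / 2, (nrow(seq$frames[[1]]) + 1) / 2)
  (pos_px - ctr) * seq$pixel_spacing_mm / (seq$sdd_cm / seq$sad_cm)
}

#' @export
print.image_sequence <- function(x, ...) {
  cat(sprintf("image_sequence '%s' (%s): %d frames %dx%d px, %.3g mm/px\n",
              x$dataset_id, x$domain, length(x$frames),
              nrow(x$frames[[1]]), ncol(x$frames[[1]]), x$pixel_spacing_mm))
  invisible(x)
}

#' Extract one energy stream (or check alternation)
#' @param seq an `image_sequence`.
#' @param energy `"HE"` or `"LE"`.
#' @return an `image_sequence` containing only that stream.
#' @export
energy_stream <- function(seq, energy) {
  keep <- seq$meta$energy == energy
  out <- seq
  out$frames <- seq$frames[keep]
  out$meta <- seq$meta[keep, , drop = FALSE]
  out$true_trajectory <- seq$true_trajectory[keep, , drop = FALSE]
  out
}
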