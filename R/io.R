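#' Write an image sequence as multi-page TIFF + JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages scaled to `[0, 1]` by
#' the sequence maximum; the sidecar records the intensity scale,
#' geometry, per-frame metadata and (if present) the true trajectory,
#' so [read_sequence()] round-trips the object.
#'
#' @param seq an `image_sequence`.
#' @param prefix file path prefix; writes `<prefix>.tif` and
#'   `<prefix>.json`.
#' @return the prefix, invisibly.
#' @export
write_sequence <- function(seq, prefix) {
  scale <- max(vapply(seq$frames, max, numeric(1)))
  if (scale <= 0) scale <- 1
  tiff::writeTIFF(lapply(seq$frames, function(f) f / scale),
                  paste0(prefix, ".tif"), bits.per.sample = 32L)
  sidecar <- list(
    dataset_id = seq$dataset_id, domain = seq$domain,
    pixel_spacing_mm = seq$pixel_spacing_mm,
    sdd_cm = seq$sdd_cm, sad_cm = seq$sad_cm,
    intensity_scale = scale,
    frames = seq$meta,
    true_trajectory = seq$true_trajectory
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read an image sequence written by [write_sequence()]
#' @param prefix path prefix used at write time.
#' @return an `image_sequence`.
#' @export
read_sequence <- function(prefix) {
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  frames <- lapply(pages, function(p) p * side$intensity_scale)
  structure(list(
    frames = frames,
    meta = as.data.frame(side$frames),
    pixel_spacing_mm = side$pixel_spacing_mm,
    sdd_cm = side$sdd_cm, sad_cm = side$sad_cm,
    dataset_id = side$dataset_id, domain = side$domain,
    true_trajectory = if (!is.null(side$true_trajectory))
      as.data.frame(side$true_trajectory) else NULL
  ), class = "image_sequence")
}

#' Write a track series as CSV
#' @param track a `track_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_series <- function(track, path) {
  out <- cbind(dataset_id = attr(track, "dataset_id"),
               modality = attr(track, "modality"),
               as.data.frame(track))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a track series CSV
#' @param path CSV written by [write_track_series()].
#' @return a `track_series`.
#' @export
read_track_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- df[setdiff(names(df), c("dataset_id", "modality"))]
  dt <- if (nrow(out) > 1) stats::median(diff(out$t_s)) else NA_real_
  structure(out, class = c("track_series", "data.frame"),
            dataset_id = df$dataset_id[1], modality = df$modality[1],
            effective_dt_s = dt)
}

#' Write a reference trajectory as CSV
#' @param traj a `trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  out <- cbind(as.data.frame(traj), source = attr(traj, "source"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#' @param path CSV written by [write_trajectory()].
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  src <- df$source[1]
  df$source <- NULL
  structure(df, class = c("trajectory", "data.frame"), source = src)
}

#' Serialize a fitted reliability model as JSON
#' @param fit a `model_fit` from [loo_cv()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_fit <- function(fit, path) {
  out <- list(beta0 = fit$beta0, betas = as.list(fit$betas),
              thresholds = as.list(fit$thresholds),
              target_specificity = fit$target_specificity,
              hyper = unclass(fit$hyper), scheme = unclass(fit$scheme),
              scalers = fit$scalers$state,
              fold_aucs = as.list(fit$fold_aucs),
              coef_ci = as.data.frame(fit$coef_ci))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
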