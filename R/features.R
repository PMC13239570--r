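#' Sample-weighting scheme by tracking-quality band
#'
#' Patient-like datasets contribute to the fit with a weight set by
#' their quality band; phantom data always weigh 1. The study default
#' is (good, moderate, poor) = (1.0, 0.6, 0.2), with sweep grids
#' 0.4-0.8 for moderate and 0.1-0.3 for poor.
#'
#' @param good,moderate,poor,phantom per-band weights in `(0, 1]`.
#' @return object of class `weight_scheme`.
#' @export
weight_scheme <- function(good = 1.0, moderate = 0.6, poor = 0.2,
                          phantom = 1.0) {
  w <- c(good = good, moderate = moderate, poor = poor, phantom = phantom)
  if (any(w <= 0) || any(w > 1)) stop("weights must lie in (0, 1]")
  structure(as.list(w), class = "weight_scheme")
}

#' Frame-to-frame velocities from a track series
#'
#' Central finite differences over the tracked (non-missing) frames
#' using actual timestamps; endpoints and frames adjacent to a missing
#' gap use the available one-sided difference. Units: mm/s at
#' isocenter. Gaps are never interpolated.
#'
#' @param track a `track_series`.
#' @return data.frame `frame_index`, `vx`, `vy` for tracked frames.
#' @export
velocities <- function(track) {
  keep <- which(!track$missing)
  if (length(keep) < 2) stop("need >= 2 tracked frames for velocities")
  idx <- track$frame_index[keep]
  t <- track$t_s[keep]
  x <- track$x_mm[keep]; y <- track$y_mm[keep]
  n <- length(keep)
  vx <- numeric(n); vy <- numeric(n)
  for (i in seq_len(n)) {
    prev_ok <- i > 1 && idx[i] - idx[i - 1] == 1L
    next_ok <- i < n && idx[i + 1] - idx[i] == 1L
    if (!prev_ok && !next_ok) {        # isolated between gaps: nearest side
      prev_ok <- i > 1; next_ok <- i < n
      if (prev_ok && next_ok) {        # choose the temporally closer side
        if (t[i] - t[i - 1] <= t[i + 1] - t[i]) next_ok <- FALSE
        else prev_ok <- FALSE
      }
    }
    lo <- if (prev_ok) i - 1 else i
    hi <- if (next_ok) i + 1 else i
    dt <- t[hi] - t[lo]
    vx[i] <- (x[hi] - x[lo]) / dt
    vy[i] <- (y[hi] - y[lo]) / dt
  }
  data.frame(frame_index = idx, vx = vx, vy = vy)
}

#' Assemble per-frame features for one tracked dataset
#'
#' Joins tracking confidence (match score, PSR), velocities and
#' reliability labels into the unscaled feature table; rows from
#' missing frames are dropped.
#'
#' @param track a `track_series`.
#' @param tsr_result the [tsr()] result for the same series (its
#'   per-frame labels are the targets).
#' @param domain `"phantom"` or `"patient"`.
#' @return data.frame with columns `dataset_id`, `modality`, `domain`,
#'   `di`, `frame_index`, `t_s`, `match_score`, `psr`, `vx`, `vy`,
#'   `label`.
#' @export
frame_features <- function(track, tsr_result, domain = c("phantom", "patient")) {
  domain <- match.arg(domain)
  v <- velocities(track)
  keep <- !track$missing
  df <- data.frame(
    dataset_id = attr(track, "dataset_id"),
    modality = attr(track, "modality"),
    domain = domain, di = as.integer(domain == "patient"),
    frame_index = track$frame_index[keep], t_s = track$t_s[keep],
    match_score = track$match_score[keep], psr = track$psr[keep],
    stringsAsFactors = FALSE)
  df$vx <- v$vx[match(df$frame_index, v$frame_index)]
  df$vy <- v$vy[match(df$frame_index, v$frame_index)]
  lab <- tsr_result$frames
  df$label <- lab$label[match(df$frame_index, lab$frame_index)]
  df
}

#' Fit feature scalers on training rows
#'
#' The match score is standardized (subtract mean, divide by the
#' population standard deviation); PSR and the two velocities, which
#' are outlier-prone, are robust-scaled (subtract median, divide by
#' IQR). Scalers are fit per domain by default, since the model
#' calibrates phantom and patient-like populations separately. A zero
#' IQR falls back to the population sd (with a warning); a zero sd
#' falls back to 1.
#'
#' @param df training feature table from [frame_features()].
#' @param per_domain logical; fit separate states for phantom and
#'   patient rows (pooled fitting when `FALSE`).
#' @return object of class `scaler_state`.
#' @export
fit_scalers <- function(df, per_domain = TRUE) {
  fit_one <- function(d) {
    pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
    robust <- function(v) {
      ctr <- stats::median(v)
      sc <- stats::IQR(v)
      if (sc == 0) {
        warning("zero IQR: falling back to sd-based scale")
        sc <- pop_sd(v)
      }
      if (sc == 0) sc <- 1
      c(center = ctr, scale = sc)
    }
    ms_sd <- pop_sd(d$match_score)
    list(match_score = c(center = mean(d$match_score),
                         scale = if (ms_sd > 0) ms_sd else 1),
         psr = robust(d$psr), vx = robust(d$vx), vy = robust(d$vy))
  }
  state <- if (per_domain) {
    doms <- unique(df$domain)
    stats::setNames(lapply(doms, function(dm)
      fit_one(df[df$domain == dm, , drop = FALSE])), doms)
  } else {
    list(pooled = fit_one(df))
  }
  structure(list(per_domain = per_domain, state = state),
            class = "scaler_state")
}

#' Apply a fitted scaler state
#'
#' Transforms `match_score`, `psr`, `vx`, `vy` into the scaled model
#' features `x1..x4` using the stored statistics verbatim (never
#' refit), so validation and test rows are scaled by training
#' statistics only.
#'
#' @param df feature table.
#' @param scalers a [fit_scalers()] state.
#' @return `df` with added columns `x1`, `x2`, `x3`, `x4`.
#' @export
apply_scalers <- function(df, scalers) {
  key <- function(dm) {
    if (!scalers$per_domain) return("pooled")
    if (!dm %in% names(scalers$state))
      stop("no scaler state for domain ", dm)
    dm
  }
  sc <- function(v, st) (v - st[["center"]]) / st[["scale"]]
  df$x1 <- df$x2 <- df$x3 <- df$x4 <- NA_real_
  for (dm in unique(df$domain)) {
    st <- scalers$state[[key(dm)]]
    r <- df$domain == dm
    df$x1[r] <- sc(df$match_score[r], st$match_score)
    df$x2[r] <- sc(df$psr[r], st$psr)
    df$x3[r] <- sc(df$vx[r], st$vx)
    df$x4[r] <- sc(df$vy[r], st$vy)
  }
  df
}

#' Design matrix with domain-indicator interactions
#'
#' Columns in the fixed reporting order x1, x2, x3, x4, DI, DI.x1,
#' DI.x2, DI.x3, DI.x4 (matching coefficients beta1..beta9); phantom
#' rows (DI = 0) have the last five columns all zero, so the first
#' five terms are the phantom baseline model and the interactions let
#' the fit adapt each feature's coefficient to the patient domain.
#'
#' @param df scaled, labeled feature table (see [apply_scalers()]).
#' @return list: `x` (n x 9 matrix), `y` (0/1 labels), `weights`
#'   (or NULL if absent), `dataset_id`.
#' @export
build_design_matrix <- function(df) {
  need <- c("x1", "x2", "x3", "x4", "di", "label")
  if (!all(need %in% names(df))) stop("frames not fully featured/scaled")
  if (anyNA(df$label)) stop("unlabeled frame in feature table")
  x <- cbind(x1 = df$x1, x2 = df$x2, x3 = df$x3, x4 = df$x4, DI = df$di,
             DI.x1 = df$di * df$x1, DI.x2 = df$di * df$x2,
             DI.x3 = df$di * df$x3, DI.x4 = df$di * df$x4)
  list(x = x, y = as.integer(df$label),
       weights = if ("weight" %in% names(df)) df$weight else NULL,
       dataset_id = df$dataset_id)
}

#' Assign per-frame sample weights from dataset quality bands
#'
#' @param df feature table.
#' @param quality_by_dataset named character vector mapping each
#'   patient-like `dataset_id` to its band (`"good"`, `"moderate"`,
#'   `"poor"`).
#' @param scheme a [weight_scheme()].
#' @return `df` with a `weight` column (phantom rows weigh
#'   `scheme$phantom`).
#' @export
assign_weights <- function(df, quality_by_dataset, scheme = weight_scheme()) {
  df$weight <- NA_real_
  ph <- df$domain == "phantom"
  df$weight[ph] <- scheme$phantom
  for (id in unique(df$dataset_id[!ph])) {
    band <- if (id %in% names(quality_by_dataset))
      quality_by_dataset[[id]] else NULL
    if (is.null(band) || is.na(band))
      stop("no quality band for dataset ", id)
    df$weight[df$dataset_id == id & !ph] <- scheme[[band]]
  }
  df
}
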