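# Independent brute-force oracles used to check the implementation.

# double-loop masked ZNCC at given 1-based top-left corners
brute_ncc <- function(image, patch, mask, row_starts, col_starts) {
  out <- matrix(0, length(row_starts), length(col_starts))
  tv <- patch[mask]
  tc <- tv - mean(tv)
  tn <- sqrt(sum(tc^2))
  for (i in seq_along(row_starts)) for (j in seq_along(col_starts)) {
    sub <- image[row_starts[i] + 0:(nrow(patch) - 1),
                 col_starts[j] + 0:(ncol(patch) - 1)]
    iv <- sub[mask]
    ic <- iv - mean(iv)
    inorm <- sqrt(sum(ic^2))
    out[i, j] <- if (inorm <= 1e-8 || tn <= 1e-8) 0 else
      sum(tc * ic) / (tn * inorm)
  }
  out
}

# exhaustive argmax with smallest-row-then-column tie-break
brute_argmax <- function(surface) {
  best <- -Inf; pk <- c(NA, NA)
  for (j in seq_len(ncol(surface))) for (i in seq_len(nrow(surface))) {
    v <- surface[i, j]
    if (v > best || (v == best && (i < pk[1] || (i == pk[1] && j < pk[2])))) {
      best <- v; pk <- c(i, j)
    }
  }
  list(peak = pk, score = best)
}

# exhaustive operating-point search: smallest cutoff (over all score
# values and midpoints) whose specificity >= target
brute_threshold <- function(scores, labels, target) {
  labels <- as.integer(labels)
  neg <- scores[labels == 0]
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, u, (u[-1] + u[-length(u)]) / 2)))
  for (c0 in cand) if (mean(neg < c0) >= target) return(c0)
  max(scores) + 1e-9
}

# draw a feature table + design matrix from the domain-adapted
# logistic model with known coefficients (Bernoulli labels only)
simulate_lr_design <- function(n_per_domain, beta0, betas, seed) {
  set.seed(seed)
  n <- 2 * n_per_domain
  di <- rep(c(0L, 1L), each = n_per_domain)
  x <- matrix(rnorm(n * 4), n, 4)
  X <- cbind(x, di, di * x)
  colnames(X) <- c("x1", "x2", "x3", "x4", "DI",
                   "DI.x1", "DI.x2", "DI.x3", "DI.x4")
  p <- 1 / (1 + exp(-(beta0 + drop(X %*% betas))))
  y <- rbinom(n, 1, p)
  list(x = X, y = y, p = p, di = di)
}

# same population expressed as an unscaled feature table for loo_cv
simulate_lr_frames <- function(n_per_dataset, datasets_per_domain,
                               beta0, betas, seed) {
  set.seed(seed)
  rows <- list()
  k <- 0
  for (dom in c("phantom", "patient")) for (d in seq_len(datasets_per_domain)) {
    k <- k + 1
    di <- as.integer(dom == "patient")
    x <- matrix(rnorm(n_per_dataset * 4), n_per_dataset, 4)
    X <- cbind(x, di, di * x)
    p <- 1 / (1 + exp(-(beta0 + drop(X %*% betas))))
    rows[[k]] <- data.frame(
      dataset_id = sprintf("%s%02d", substr(dom, 1, 2), d),
      modality = "SE", domain = dom, di = di,
      frame_index = seq_len(n_per_dataset),
      t_s = seq_len(n_per_dataset) / 7.5,
      match_score = x[, 1], psr = x[, 2], vx = x[, 3], vy = x[, 4],
      label = rbinom(n_per_dataset, 1, p) == 1,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
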