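#' Hyperparameters of the penalized weighted logistic model
#'
#' The model minimizes the sample-weighted cross-entropy plus
#' `lambda * R(w)` over the coefficients (intercept unpenalized),
#' with `R` an L1, L2 or elastic-net penalty. Two optimizers honor the
#' same loss: `"fista"`, a deterministic accelerated proximal-gradient
#' scheme, and `"saga"`, a seeded stochastic average-gradient scheme.
#'
#' @param lambda regularization strength (>= 0).
#' @param penalty `"l2"`, `"l1"` or `"elastic_net"`.
#' @param l1_ratio elastic-net mixing in `[0, 1]` (1 = pure L1).
#' @param solver `"fista"` or `"saga"`.
#' @param max_iter iteration (fista) / epoch (saga) budget.
#' @param tol convergence tolerance on the proximal-gradient residual.
#' @param seed seed for the stochastic solver.
#' @return object of class `lr_hyper`.
#' @export
lr_hyper <- function(lambda = 0.01, penalty = c("l2", "l1", "elastic_net"),
                     l1_ratio = 0.5, solver = c("fista", "saga"),
                     max_iter = 2000L, tol = 1e-8, seed = 1L) {
  penalty <- match.arg(penalty)
  solver <- match.arg(solver)
  if (lambda < 0) stop("lambda must be >= 0")
  if (l1_ratio < 0 || l1_ratio > 1) stop("l1_ratio must be in [0, 1]")
  structure(list(lambda = lambda, penalty = penalty, l1_ratio = l1_ratio,
                 solver = solver, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed)),
            class = "lr_hyper")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# split lambda into smooth (ridge) and nonsmooth (lasso) parts
penalty_split <- function(hyper) {
  switch(hyper$penalty,
    l2 = c(l2 = hyper$lambda, l1 = 0),
    l1 = c(l2 = 0, l1 = hyper$lambda),
    elastic_net = c(l2 = hyper$lambda * (1 - hyper$l1_ratio),
                    l1 = hyper$lambda * hyper$l1_ratio))
}

soft_threshold <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

# full objective: weighted cross-entropy (normalized by sum of
# weights) + lambda * R(coefs); theta = c(beta0, betas)
lr_objective <- function(theta, x, y, w, hyper) {
  p <- sigmoid(theta[1] + drop(x %*% theta[-1]))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ce <- -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
  pen <- penalty_split(hyper)
  ce + pen[["l2"]] * sum(theta[-1]^2) + pen[["l1"]] * sum(abs(theta[-1]))
}

# gradient of the smooth part (cross-entropy + ridge component)
lr_smooth_grad <- function(theta, x, y, w, l2) {
  p <- sigmoid(theta[1] + drop(x %*% theta[-1]))
  r <- w * (p - y) / sum(w)
  c(sum(r), drop(crossprod(x, r)) + 2 * l2 * theta[-1])
}

#' Fit the weighted, regularized logistic model
#'
#' Minimizes the sample-weighted cross-entropy (normalized by the sum
#' of weights, so duplicating a row and doubling its weight are
#' equivalent) plus `lambda * R(coefficients)`; the intercept is never
#' penalized. Deterministic given the hyperparameters' seed.
#'
#' @param x design matrix (n x p), e.g. from [build_design_matrix()].
#' @param y 0/1 labels.
#' @param weights positive sample weights (default all 1).
#' @param hyper an [lr_hyper()].
#' @return object of class `lr_fit`: `beta0`, `betas` (named by the
#'   design columns), `converged`, `grad_norm`, `n_iter`, `hyper`.
#' @export
fit_weighted_lr <- function(x, y, weights = NULL, hyper = lr_hyper()) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x); p <- ncol(x)
  if (length(unique(y)) < 2) stop("single-class input: cannot fit")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be > 0")
  pen <- penalty_split(hyper)
  fitted <- switch(hyper$solver,
    fista = lr_fista(x, y, weights, hyper, pen),
    saga = lr_saga(x, y, weights, hyper, pen))
  theta <- fitted$theta
  res <- prox_residual(theta, x, y, weights, pen)
  if (res > max(hyper$tol, 1e-5) * 100)
    warning(sprintf("fit may not have converged (residual %.2e after %d iterations)",
                    res, fitted$n_iter))
  cn <- colnames(x)
  structure(list(beta0 = theta[1],
                 betas = stats::setNames(theta[-1],
                                         if (is.null(cn)) paste0("b", seq_len(p)) else cn),
                 converged = res <= max(hyper$tol, 1e-5) * 100,
                 grad_norm = res, n_iter = fitted$n_iter, hyper = hyper),
            class = "lr_fit")
}

# sup-norm of the proximal-gradient mapping at unit step / L
prox_residual <- function(theta, x, y, w, pen) {
  L <- lipschitz_const(x, w, pen[["l2"]])
  g <- lr_smooth_grad(theta, x, y, w, pen[["l2"]])
  z <- theta - g / L
  z[-1] <- soft_threshold(z[-1], pen[["l1"]] / L)
  max(abs(theta - z)) * L
}

lipschitz_const <- function(x, w, l2) {
  a <- cbind(1, x) * sqrt(w / sum(w))
  0.25 * max(eigen(crossprod(a), symmetric = TRUE, only.values = TRUE)$values) +
    2 * l2
}

lr_fista <- function(x, y, w, hyper, pen) {
  p <- ncol(x)
  L <- lipschitz_const(x, w, pen[["l2"]])
  theta <- numeric(p + 1)
  z <- theta; tk <- 1
  for (it in seq_len(hyper$max_iter)) {
    g <- lr_smooth_grad(z, x, y, w, pen[["l2"]])
    theta_new <- z - g / L
    theta_new[-1] <- soft_threshold(theta_new[-1], pen[["l1"]] / L)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- theta_new + (tk - 1) / t_new * (theta_new - theta)
    moved <- max(abs(theta_new - theta))
    theta <- theta_new; tk <- t_new
    if (moved * L <= hyper$tol && it > 10) break
  }
  list(theta = theta, n_iter = it)
}

lr_saga <- function(x, y, w, hyper, pen) {
  n <- nrow(x); p <- ncol(x)
  a <- cbind(1, x)
  sw <- sum(w)
  theta <- numeric(p + 1)
  # stored per-sample derivative scalars of the (weight-normalized) loss
  d <- w * (sigmoid(drop(a %*% theta)) - y) / sw
  avg <- drop(crossprod(a, d))           # mean gradient times n... (sum)
  Lmax <- 0.25 * max(rowSums(a^2) * w) / sw * n + 2 * pen[["l2"]]
  eta <- 1 / (3 * Lmax)
  rng <- local_rng(hyper$seed)
  it <- 0L
  for (ep in seq_len(hyper$max_iter)) {
    js <- rng$int(n, n)
    for (j in js) {
      dj_new <- w[j] * (sigmoid(sum(a[j, ] * theta)) - y[j]) / sw
      g <- (dj_new - d[j]) * n * a[j, ] + avg +
        2 * pen[["l2"]] * c(0, theta[-1])
      avg <- avg + (dj_new - d[j]) * a[j, ]
      d[j] <- dj_new
      theta <- theta - eta * g
      theta[-1] <- soft_threshold(theta[-1], eta * pen[["l1"]])
    }
    it <- ep
    if (prox_residual(theta, x, y, w, pen) <= hyper$tol) break
  }
  list(theta = theta, n_iter = it)
}

#' Predicted reliability probabilities
#' @param fit an `lr_fit`.
#' @param x design matrix with the fit's column order.
#' @return numeric vector of probabilities.
#' @export
predict_lr <- function(fit, x) {
  sigmoid(fit$beta0 + drop(as.matrix(x) %*% fit$betas))
}

#' Operating threshold at a target specificity
#'
#' The smallest probability cutoff whose training specificity (with
#' prediction "reliable" when score >= cutoff) is at least the target;
#' being the smallest qualifying cutoff it also has the highest
#' sensitivity among qualifying cutoffs. Computed per domain by the
#' cross-validation driver.
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 (or logical) reliability labels.
#' @param target_specificity target in `[0, 1]`.
#' @param weights optional sample weights; when given, specificity is
#'   the weighted fraction of negatives below the cutoff, so
#'   low-confidence (down-weighted) labels influence the operating
#'   point less.
#' @return scalar threshold.
#' @export
select_threshold <- function(scores, labels, target_specificity = 0.95,
                             weights = NULL) {
  labels <- as.integer(labels)
  if (is.null(weights)) weights <- rep(1, length(scores))
  neg <- labels == 0
  if (!any(neg)) stop("no negatives: target specificity unreachable")
  wneg <- weights[neg]; sneg <- scores[neg]
  cand <- sort(unique(c(0, scores)))
  for (c0 in cand) {
    if (sum(wneg[sneg < c0]) / sum(wneg) >= target_specificity)
      return(c0)
  }
  # only a cutoff above every score reaches the target
  max(scores) + 1e-9
}

#' Average per-fold thresholds into the final cutoff
#' @param thresholds numeric vector (one per fold) or a matrix/
#'   data.frame with one column per domain; `NA` entries (folds where
#'   a domain had no negatives) are dropped.
#' @return arithmetic mean (per column when matrix-like).
#' @export
average_fold_thresholds <- function(thresholds) {
  if (is.null(dim(thresholds))) mean(thresholds, na.rm = TRUE)
  else colMeans(as.matrix(thresholds), na.rm = TRUE)
}

#' Rank-based AUC
#'
#' Area under the ROC curve via the Mann-Whitney statistic, identical
#' to trapezoidal integration of the empirical ROC over all score
#' cutoffs.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return scalar AUC, or `NA` when one class is absent.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC points
#' @inheritParams auc_score
#' @return data.frame `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  cuts <- c(-Inf, sort(unique(scores)), Inf)
  do.call(rbind, lapply(cuts, function(c0) {
    pred <- scores >= c0
    data.frame(threshold = c0,
               fpr = if (any(labels == 0)) mean(pred[labels == 0]) else NA,
               tpr = if (any(labels == 1)) mean(pred[labels == 1]) else NA)
  }))
}

#' Confusion counts and the printed sensitivity/specificity formulas
#'
#' Sensitivity = TP / (TP + FN); specificity = 1 - FP / (TN + FP)
#' (algebraically TN / (TN + FP)). Metrics whose denominator is zero
#' are reported as `NA`, not 0.
#'
#' @param tp,fp,tn,fn counts.
#' @return list of class `confusion_report`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 1 - fp / (tn + fp) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec),
            class = "confusion_report")
}

#' Evaluate a fitted model on labeled frames
#'
#' Predicts reliable when the modeled probability is at least the
#' operating threshold (per-domain thresholds supported), then builds
#' the confusion report, the printed-formula metrics, and the
#' rank-based AUC.
#'
#' @param fit an `lr_fit`.
#' @param df scaled, labeled feature table.
#' @param threshold scalar cutoff, or named vector by domain
#'   (e.g. `c(phantom = 0.54, patient = 0.85)`).
#' @return a `confusion_report` with `auc` and `threshold` fields.
#' @export
evaluate_model <- function(fit, df, threshold) {
  dm <- build_design_matrix(df)
  scores <- predict_lr(fit, dm$x)
  thr <- if (length(threshold) == 1) rep(as.numeric(threshold), nrow(df))
         else as.numeric(threshold[df$domain])
  if (anyNA(thr)) stop("threshold missing for some domain")
  pred <- scores >= thr
  y <- dm$y == 1
  rep <- confusion_metrics(tp = sum(pred & y), fp = sum(pred & !y),
                           tn = sum(!pred & !y), fn = sum(!pred & y))
  rep$auc <- auc_score(scores, y)
  rep$threshold <- threshold
  rep$scores <- scores
  rep$pred <- pred
  rep
}

#' Leave-one-dataset-out cross-validation
#'
#' Each patient-like dataset is held out once as validation (phantom
#' data stay in every training set); per fold, scalers are refit on
#' training rows only, the weighted model is refit, and per-domain
#' thresholds are selected on training rows at the target specificity.
#' Fold thresholds are averaged into the final cutoffs; the final
#' coefficients come from a fit on all training data, with 2.5/97.5
#' percentile intervals across the fold fits.
#'
#' @param df unscaled feature table (all training datasets).
#' @param quality_by_dataset named band per patient-like dataset.
#' @param hyper an [lr_hyper()].
#' @param scheme a [weight_scheme()].
#' @param target_specificity operating-point target.
#' @param per_domain_scalers passed to [fit_scalers()].
#' @param fold_datasets datasets to use as validation folds (default:
#'   all patient-domain datasets in `df`).
#' @return object of class `model_fit`.
#' @export
loo_cv <- function(df, quality_by_dataset, hyper = lr_hyper(),
                   scheme = weight_scheme(), target_specificity = 0.95,
                   per_domain_scalers = TRUE, fold_datasets = NULL) {
  if (is.null(fold_datasets))
    fold_datasets <- unique(df$dataset_id[df$domain == "patient"])
  if (length(fold_datasets) < 1) stop("no validation folds")
  df <- assign_weights(df, quality_by_dataset, scheme)

  folds <- list()
  for (d in fold_datasets) {
    train <- df[df$dataset_id != d, , drop = FALSE]
    valid <- df[df$dataset_id == d, , drop = FALSE]
    if (length(unique(train$label)) < 2) {
      warning("fold ", d, " skipped: training set lost a class")
      next
    }
    scalers <- fit_scalers(train, per_domain = per_domain_scalers)
    train_s <- apply_scalers(train, scalers)
    valid_s <- apply_scalers(valid, scalers)
    dmt <- build_design_matrix(train_s)
    fit <- fit_weighted_lr(dmt$x, dmt$y, dmt$weights, hyper)
    scores_t <- predict_lr(fit, dmt$x)
    thr <- vapply(unique(train_s$domain), function(dm) {
      r <- train_s$domain == dm
      tryCatch(
        select_threshold(scores_t[r], dmt$y[r], target_specificity,
                         weights = dmt$weights[r]),
        error = function(e) {
          warning("fold ", d, ", domain ", dm, ": ", conditionMessage(e))
          NA_real_
        })
    }, numeric(1))
    dmv <- build_design_matrix(valid_s)
    scores_v <- predict_lr(fit, dmv$x)
    thr_v <- thr[[unique(valid_s$domain)]]
    pred_v <- if (is.na(thr_v)) rep(NA, length(scores_v))
              else scores_v >= thr_v
    yv <- dmv$y == 1
    folds[[d]] <- list(
      dataset = d, fit = fit, thresholds = thr,
      auc_valid = auc_score(scores_v, yv),
      sens_valid = if (any(yv)) mean(pred_v[yv]) else NA_real_,
      spec_valid = if (any(!yv)) 1 - mean(pred_v[!yv]) else NA_real_,
      valid_pred = data.frame(dataset_id = d,
                              frame_index = valid_s$frame_index,
                              score = scores_v, pred = pred_v,
                              label = yv))
  }
  if (length(folds) == 0) stop("all folds skipped")

  thr_mat <- do.call(rbind, lapply(folds, function(f)
    f$thresholds[c("phantom", "patient")[c("phantom", "patient") %in% names(f$thresholds)]]))
  final_thr <- average_fold_thresholds(thr_mat)
  if (anyNA(final_thr)) {
    # a domain with no unreliable training frames in any fold satisfies
    # the specificity target vacuously; the ties-toward-sensitivity rule
    # then picks the smallest cutoff
    warning("no negatives in any fold for domain(s) ",
            paste(names(final_thr)[is.na(final_thr)], collapse = ", "),
            ": operating threshold set to 0")
    final_thr[is.na(final_thr)] <- 0
  }

  scalers <- fit_scalers(df, per_domain = per_domain_scalers)
  df_s <- apply_scalers(df, scalers)
  dm <- build_design_matrix(df_s)
  final_fit <- fit_weighted_lr(dm$x, dm$y, dm$weights, hyper)

  coef_mat <- do.call(rbind, lapply(folds, function(f)
    c(beta0 = f$fit$beta0, f$fit$betas)))
  ci <- apply(coef_mat, 2, stats::quantile, probs = c(0.025, 0.975))
  aucs <- vapply(folds, function(f) f$auc_valid, numeric(1))

  structure(list(
    beta0 = final_fit$beta0, betas = final_fit$betas,
    thresholds = final_thr, scalers = scalers, hyper = hyper,
    scheme = scheme, target_specificity = target_specificity,
    folds = folds, fold_thresholds = thr_mat, coef_ci = ci,
    fold_aucs = aucs,
    auc_ci = stats::quantile(aucs[!is.na(aucs)], c(0.025, 0.975)),
    fit = final_fit
  ), class = "model_fit")
}

#' Sweep sample-weight and hyperparameter grids
#'
#' Runs [loo_cv()] for every grid point and selects the point with the
#' highest mean validation sensitivity among points whose mean
#' validation specificity is at least the target; if no point meets
#' the constraint, the best-specificity point is returned with a
#' warning. The study's grids are moderate 0.4-0.8 (step 0.1) and
#' poor 0.1-0.3 (step 0.05).
#'
#' @inheritParams loo_cv
#' @param moderate_grid,poor_grid weight grids.
#' @param hyper_grid list of [lr_hyper()] objects.
#' @return list: `scheme`, `hyper`, `cv` (winning [loo_cv()] result),
#'   `table` (full sweep log).
#' @export
sweep_weights_and_hyper <- function(df, quality_by_dataset,
                                    moderate_grid = seq(0.4, 0.8, by = 0.1),
                                    poor_grid = seq(0.1, 0.3, by = 0.05),
                                    hyper_grid = list(lr_hyper()),
                                    target_specificity = 0.95) {
  stopifnot(length(moderate_grid) > 0, length(poor_grid) > 0,
            length(hyper_grid) > 0)
  rows <- list(); fits <- list(); k <- 0L
  for (hm in seq_along(hyper_grid)) for (wm in moderate_grid)
    for (wp in poor_grid) {
      k <- k + 1L
      sch <- weight_scheme(moderate = wm, poor = wp)
      cv <- loo_cv(df, quality_by_dataset, hyper = hyper_grid[[hm]],
                   scheme = sch, target_specificity = target_specificity)
      sens <- mean(vapply(cv$folds, `[[`, numeric(1), "sens_valid"),
                   na.rm = TRUE)
      spec <- mean(vapply(cv$folds, `[[`, numeric(1), "spec_valid"),
                   na.rm = TRUE)
      rows[[k]] <- data.frame(hyper = hm, moderate = wm, poor = wp,
                              mean_sens = sens, mean_spec = spec)
      fits[[k]] <- list(scheme = sch, hyper = hyper_grid[[hm]], cv = cv)
    }
  tab <- do.call(rbind, rows)
  ok <- which(tab$mean_spec >= target_specificity)
  if (length(ok) == 0) {
    warning("no grid point reached the target specificity; returning the best-specificity point")
    pick <- which.max(tab$mean_spec)
  } else {
    pick <- ok[which.max(tab$mean_sens[ok])]
  }
  c(fits[[pick]], list(table = tab))
}

#' Exact McNemar test on paired frame-level predictions
#'
#' Two-sided exact binomial test on the discordant pairs (frames one
#' model classifies correctly and the other does not).
#'
#' @param correct_a,correct_b logical vectors, aligned frames.
#' @return list: `b`, `c` discordant counts and `p_value`.
#' @export
mcnemar_exact <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  p <- if (b + cc == 0) 1 else
    stats::binom.test(b, b + cc, p = 0.5)$p.value
  list(b = b, c = cc, p_value = p)
}

#' Paired SE-vs-DE modality study
#'
#' Fits independent reliability models for the SE and DE feature
#' tables over the same datasets, reports per-modality pooled
#' training sensitivity/specificity at the 95%-specificity operating
#' point, held-out per-dataset metrics, and an exact McNemar paired
#' test on the frame-level correctness of the two modality models
#' (over frames tracked in both).
#'
#' @param se_df,de_df unscaled feature tables for the two modalities.
#' @param quality_by_dataset named band per patient-like dataset.
#' @param held_out character vector of held-out dataset ids (excluded
#'   from training and CV, evaluated at the final thresholds).
#' @param hyper,scheme,target_specificity model settings.
#' @return list of class `modality_study`: per-modality `model_fit`s,
#'   training and held-out reports, and the paired comparison.
#' @export
run_modality_study <- function(se_df, de_df, quality_by_dataset,
                               held_out = character(0),
                               hyper = lr_hyper(), scheme = weight_scheme(),
                               target_specificity = 0.95) {
  ids_se <- sort(unique(se_df$dataset_id))
  ids_de <- sort(unique(de_df$dataset_id))
  if (!identical(ids_se, ids_de))
    stop("modality feature tables cover different datasets")

  one <- function(df) {
    train <- df[!df$dataset_id %in% held_out, , drop = FALSE]
    cv <- loo_cv(train, quality_by_dataset, hyper = hyper, scheme = scheme,
                 target_specificity = target_specificity)
    train_s <- apply_scalers(train, cv$scalers)
    rep_train <- evaluate_model(cv$fit, train_s, cv$thresholds)
    held <- lapply(held_out, function(d) {
      hd <- df[df$dataset_id == d, , drop = FALSE]
      hd <- assign_weights(hd, quality_by_dataset, scheme)
      hs <- apply_scalers(hd, cv$scalers)
      evaluate_model(cv$fit, hs, cv$thresholds)
    })
    names(held) <- held_out
    list(cv = cv, train = train, train_scaled = train_s,
         report_train = rep_train, held_out = held)
  }
  se <- one(se_df); de <- one(de_df)

  # paired comparison on frames tracked in both modalities
  key <- function(df) paste(df$dataset_id, df$frame_index)
  common <- intersect(key(se$train), key(de$train))
  m_se <- match(common, key(se$train)); m_de <- match(common, key(de$train))
  corr_se <- (se$report_train$pred == (se$train$label))[m_se]
  corr_de <- (de$report_train$pred == (de$train$label))[m_de]
  paired <- mcnemar_exact(corr_se, corr_de)

  structure(list(
    se = se, de = de,
    sens_se = se$report_train$sensitivity,
    sens_de = de$report_train$sensitivity,
    spec_se = se$report_train$specificity,
    spec_de = de$report_train$specificity,
    paired_test = paired, held_out_ids = held_out
  ), class = "modality_study")
}
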