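test_that("penalized weighted fit honors its limits and sign constraints", {
  set.seed(1)
  x <- matrix(rnorm(200), 100, 2)
  y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(100, sd = 0.5) > 0)

  # penalty-dominated limit crushes the coefficients
  # (the residual check scales with the penalty here; the coefficient
  # bound is the contract)
  big <- suppressWarnings(fit_weighted_lr(x, y, hyper = lr_hyper(lambda = 1e6)))
  expect_true(all(abs(big$betas) < 1e-3))

  # separable 1-D data: positive slope
  x1 <- matrix(seq(-2, 2, length.out = 40), ncol = 1)
  y1 <- as.integer(x1[, 1] > 0)
  sep <- fit_weighted_lr(x1, y1, hyper = lr_hyper(lambda = 0.1))
  expect_gt(sep$betas[1], 0)

  expect_error(fit_weighted_lr(x, rep(1L, 100)), "single-class")
  expect_error(fit_weighted_lr(x, y, weights = rep(0, 100)), "weights")
})

test_that("duplicating a row equals doubling its weight", {
  set.seed(2)
  x <- matrix(rnorm(60), 30, 2)
  y <- as.integer(x[, 1] > 0.2)
  h <- lr_hyper(lambda = 0.05, max_iter = 20000, tol = 1e-12)
  dup <- fit_weighted_lr(rbind(x, x[7, ]), c(y, y[7]), hyper = h)
  wts <- rep(1, 30); wts[7] <- 2
  wtd <- fit_weighted_lr(x, y, weights = wts, hyper = h)
  expect_lt(max(abs(c(dup$beta0 - wtd$beta0, dup$betas - wtd$betas))), 1e-8)
})

test_that("both solvers match an independent optimizer on the same loss", {
  set.seed(3)
  n <- 100
  x <- matrix(rnorm(n * 3), n, 3)
  y <- as.integer(drop(x %*% c(1, -0.5, 0.2)) + rnorm(n, sd = 0.8) > 0)
  w <- runif(n, 0.5, 2)
  lam <- 0.02
  h <- lr_hyper(lambda = lam, penalty = "l2", max_iter = 20000, tol = 1e-12)
  fit <- fit_weighted_lr(x, y, w, h)

  # oracle: direct quasi-Newton minimization of the identical objective
  obj <- function(theta) {
    p <- 1 / (1 + exp(-(theta[1] + drop(x %*% theta[-1]))))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w) +
      lam * sum(theta[-1]^2)
  }
  oracle <- stats::optim(rep(0, 4), obj, method = "BFGS",
                         control = list(maxit = 2000, reltol = 1e-14))$par
  expect_lt(max(abs(c(fit$beta0, fit$betas) - oracle)), 1e-4)

  # stochastic solver converges to the same optimum, seeded
  hs <- lr_hyper(lambda = lam, penalty = "l2", solver = "saga",
                 max_iter = 400, tol = 1e-10, seed = 4)
  saga <- fit_weighted_lr(x, y, w, hs)
  expect_lt(max(abs(c(saga$beta0, saga$betas) - oracle)), 1e-3)
  saga2 <- fit_weighted_lr(x, y, w, hs)
  expect_identical(saga$betas, saga2$betas)
})

test_that("elastic-net fit agrees with glmnet on a shared objective", {
  set.seed(5)
  n <- 300
  x <- matrix(rnorm(n * 4), n, 4)
  y <- as.integer(drop(x %*% c(1.2, -0.8, 0, 0.3)) + rnorm(n) > 0)
  lam <- 0.05
  ours <- fit_weighted_lr(x, y, hyper = lr_hyper(
    lambda = lam, penalty = "l1", max_iter = 50000, tol = 1e-12))
  g <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                      lambda = lam, standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(ours$betas - as.numeric(g$beta))), 2e-3)
  expect_lt(abs(ours$beta0 - as.numeric(g$a0)), 2e-3)
})

test_that("coefficients of the domain-adapted model are recoverable", {
  beta0 <- -0.4
  betas <- c(0.7, 1.2, -0.23, 0.02, 0.9, -0.09, -0.8, -0.27, -0.33)
  sim <- simulate_lr_design(5000, beta0, betas, seed = 7)
  fit <- fit_weighted_lr(sim$x, sim$y,
                         hyper = lr_hyper(lambda = 1e-4, max_iter = 5000,
                                          tol = 1e-10))
  expect_lt(max(abs(fit$betas - betas)), 0.1)
  expect_lt(abs(fit$beta0 - beta0), 0.1)
})

test_that("threshold selection matches an exhaustive oracle", {
  set.seed(7)
  for (k in 1:100) {
    n <- sample(20:60, 1)
    scores <- round(runif(n), 3)
    labels <- rbinom(n, 1, 0.6)
    if (sum(labels == 0) == 0) labels[1] <- 0
    target <- sample(c(0.8, 0.9, 0.95), 1)
    got <- select_threshold(scores, labels, target)
    want <- brute_threshold(scores, labels, target)
    # both cutoffs induce identical confusion counts
    expect_identical(scores >= got, scores >= want)
  }
  # perfectly separated: smallest qualifying cutoff keeps sensitivity 1
  s <- c(0.1, 0.2, 0.8, 0.9); l <- c(0, 0, 1, 1)
  thr <- select_threshold(s, l, 0.95)
  expect_equal(mean(s[l == 1] >= thr), 1.0)
  expect_true(mean(s[l == 0] < thr) >= 0.95)
  # target zero admits everything
  expect_equal(select_threshold(s, l, 0), 0)
  expect_error(select_threshold(c(0.5, 0.6), c(1, 1), 0.95), "negatives")
})

test_that("fold threshold averaging is a plain mean", {
  expect_equal(average_fold_thresholds(c(0.5, 0.6, 0.7)), 0.6)
  expect_equal(average_fold_thresholds(0.42), 0.42)
  expect_equal(average_fold_thresholds(c(0.7, 0.5, 0.6)),
               average_fold_thresholds(c(0.5, 0.6, 0.7)))
  m <- cbind(phantom = c(0.5, 0.7), patient = c(0.8, NA))
  expect_equal(unname(average_fold_thresholds(m)), c(0.6, 0.8))
})

test_that("rank AUC matches pROC and behaves at the extremes", {
  set.seed(8)
  scores <- runif(200); labels <- rbinom(200, 1, 0.5)
  expect_equal(auc_score(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE, direction = "<"))),
               tolerance = 1e-12)
  expect_equal(auc_score(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_true(is.na(auc_score(1:4, rep(1, 4))))

  roc <- roc_points(scores, labels)
  expect_true(all(diff(roc$fpr) <= 0))
  expect_true(all(diff(roc$tpr) <= 0))
})

test_that("confusion metrics reproduce the printed-count arithmetic", {
  r <- confusion_metrics(tp = 1958, fp = 1094 - 1040, tn = 1040,
                         fn = 2680 - 1958)
  expect_equal(100 * r$sensitivity, 73.1, tolerance = 0.1)
  expect_equal(100 * r$specificity, 1040 / 1094 * 100, tolerance = 1e-9)
  none <- confusion_metrics(tp = 0, fp = 2, tn = 5, fn = 0)
  expect_true(is.na(none$sensitivity))
})

test_that("specificity rises and sensitivity falls with the cutoff", {
  set.seed(9)
  scores <- runif(500)
  labels <- rbinom(500, 1, plogis(4 * scores - 2))
  grid <- seq(0, 1, by = 0.05)
  sens <- spec <- numeric(length(grid))
  for (i in seq_along(grid)) {
    pred <- scores >= grid[i]
    sens[i] <- mean(pred[labels == 1])
    spec[i] <- 1 - mean(pred[labels == 0])
  }
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("zeroed interactions reduce patients to the phantom model", {
  betas <- c(0.7, 2.6, -0.23, 0.02, 2.8, -0.09, -1.19, -0.27, -0.33)
  fit <- structure(list(beta0 = -0.4, betas = betas), class = "lr_fit")
  sim <- simulate_lr_design(50, -0.4, betas, seed = 10)
  pat <- sim$x[sim$di == 1, ]
  zeroed <- pat; zeroed[, 5:9] <- 0
  p_phantom_model <- predict_lr(fit, zeroed)
  manual <- 1 / (1 + exp(-(-0.4 + drop(pat[, 1:4] %*% betas[1:4]))))
  expect_equal(p_phantom_model, manual, tolerance = 1e-12)
})

test_that("leave-one-dataset-out folds are leak-free and deterministic", {
  betas <- c(1.5, 2, -0.3, 0.1, 1, -0.1, -0.8, -0.2, -0.3)
  df <- simulate_lr_frames(80, 3, -0.2, betas, seed = 12)
  q <- c(pa01 = "good", pa02 = "moderate", pa03 = "poor")
  h <- lr_hyper(lambda = 0.01, max_iter = 3000)
  cv <- loo_cv(df, q, hyper = h)
  expect_length(cv$folds, 3)          # one fold per patient dataset
  expect_s3_class(cv, "model_fit")
  expect_equal(dim(cv$fold_thresholds), c(3L, 2L))
  expect_length(cv$betas, 9)
  expect_true(all(cv$thresholds > 0 & cv$thresholds < 1))

  cv2 <- loo_cv(df, q, hyper = h)
  expect_identical(cv$betas, cv2$betas)
  expect_identical(cv$thresholds, cv2$thresholds)

  # leakage sentinel: a wild validation-only outlier cannot move the
  # training scaler state of its own fold
  df_out <- df
  row <- which(df_out$dataset_id == "pa03")[1]
  df_out[row, c("match_score", "psr", "vx", "vy")] <- 1e6
  cv3 <- loo_cv(df_out, q, hyper = h)
  f_ref <- cv$folds[["pa03"]]; f_out <- cv3$folds[["pa03"]]
  expect_identical(f_ref$fit$betas, f_out$fit$betas)
  expect_identical(f_ref$thresholds, f_out$thresholds)

  # a fold whose training set loses a class is skipped with a warning
  df_one <- df
  df_one$label[df_one$dataset_id != "pa01"] <- TRUE
  expect_warning(
    expect_error(loo_cv(df_one, q, hyper = h, fold_datasets = "pa01"),
                 "skipped"),
    "skipped")
})

test_that("weight/hyper sweep logs the grid and returns the single point", {
  betas <- c(1.5, 2, -0.3, 0.1, 1, -0.1, -0.8, -0.2, -0.3)
  df <- simulate_lr_frames(60, 3, -0.2, betas, seed = 14)
  q <- c(pa01 = "good", pa02 = "moderate", pa03 = "poor")
  out <- sweep_weights_and_hyper(
    df, q, moderate_grid = 0.6, poor_grid = 0.2,
    hyper_grid = list(lr_hyper(lambda = 0.01, max_iter = 2000)),
    target_specificity = 0.5)
  expect_equal(out$scheme$moderate, 0.6)
  expect_equal(out$scheme$poor, 0.2)
  expect_equal(nrow(out$table), 1)
  expect_s3_class(out$cv, "model_fit")
})

test_that("exact McNemar reduces to a binomial test on discordant pairs", {
  a <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 10))
  b <- c(rep(FALSE, 8), rep(TRUE, 2), rep(TRUE, 10))
  got <- mcnemar_exact(a, b)
  expect_equal(got$b, 8); expect_equal(got$c, 2)
  expect_equal(got$p_value, stats::binom.test(8, 10, 0.5)$p.value)
  same <- mcnemar_exact(a, a)
  expect_equal(same$p_value, 1)
})
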