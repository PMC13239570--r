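mk_track <- function(y, x = rep(0, length(y)), missing = rep(FALSE, length(y)),
                     dt = 1 / 7.5) {
  structure(data.frame(
    frame_index = seq_along(y), t_s = (seq_along(y) - 1) * dt,
    x_mm = x, y_mm = y, match_score = 0.8, psr = 4, missing = missing),
    class = c("track_series", "data.frame"),
    dataset_id = "toy", modality = "SE", effective_dt_s = dt)
}

test_that("velocities use central differences with one-sided fallbacks", {
  v <- velocities(mk_track(rep(1, 6)))
  expect_true(all(v$vx == 0 & v$vy == 0))

  dt <- 1 / 7.5
  t <- (0:9) * dt
  v2 <- velocities(mk_track(3 * t))
  expect_equal(v2$vy, rep(3, 10), tolerance = 1e-12)
  expect_true(all(v2$vx == 0))

  # sampled sinusoid: max central-difference slope matches the
  # attenuated analytic derivative
  T_ <- 4; A <- 10
  tt <- seq(0, 8, by = dt)
  v3 <- velocities(mk_track(A * sin(2 * pi * tt / T_), dt = dt))
  w <- 2 * pi / T_
  expected <- A * w * sin(w * dt) / (w * dt)
  expect_equal(max(abs(v3$vy)), expected, tolerance = 0.05 * expected)

  # a gap forces the available one-sided difference
  miss <- rep(FALSE, 10); miss[5] <- TRUE
  v4 <- velocities(mk_track(3 * t, missing = miss))
  expect_equal(nrow(v4), 9)
  expect_equal(v4$vy, rep(3, 9), tolerance = 1e-12)
  expect_error(velocities(mk_track(c(1, 2), missing = c(TRUE, TRUE))),
               "tracked")
})

test_that("standard and robust scalers match their worked examples", {
  df <- data.frame(domain = "phantom", match_score = c(1, 2, 3),
                   psr = c(1, 2, 3), vx = c(0, 1, 2), vy = c(5, 6, 7))
  st <- fit_scalers(df)
  out <- apply_scalers(df, st)
  expect_equal(out$x1, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  dfo <- data.frame(domain = "phantom", match_score = c(1, 2, 3, 100),
                    psr = c(1, 2, 3, 100), vx = 1:4, vy = 1:4)
  sto <- fit_scalers(dfo)
  expect_equal(sto$state$phantom$psr[["center"]], 2.5)  # outlier-immune

  # state is reapplied verbatim, never refit
  new <- data.frame(domain = "phantom", match_score = c(10, 20),
                    psr = c(10, 20), vx = c(1, 1), vy = c(1, 1))
  applied <- apply_scalers(new, st)
  expect_equal(applied$x1, (c(10, 20) - 2) / sqrt(2 / 3), tolerance = 1e-9)

  # zero IQR falls back to an sd-based scale with a warning
  dfz <- data.frame(domain = "phantom", match_score = c(1, 2, 3, 4),
                    psr = c(5, 5, 5, 5), vx = 1:4, vy = 1:4)
  expect_warning(fit_scalers(dfz), "IQR")
})

test_that("no leakage: validation-only outliers leave training scaling alone", {
  set.seed(13)
  train <- data.frame(domain = "patient", match_score = rnorm(50),
                      psr = rexp(50), vx = rnorm(50), vy = rnorm(50))
  st <- fit_scalers(train)
  ref <- apply_scalers(train, st)
  valid <- data.frame(domain = "patient", match_score = 1e6,
                      psr = 1e6, vx = 1e6, vy = 1e6)
  again <- apply_scalers(train, st)       # after seeing the outlier
  expect_identical(ref$x1, again$x1)
  scaled_out <- apply_scalers(valid, st)  # uses stored stats verbatim
  expect_gt(scaled_out$x1, 1e5)
})

test_that("design matrix fixes the column order and interaction identity", {
  df <- data.frame(
    dataset_id = c("ph", "pt"), modality = "SE",
    domain = c("phantom", "patient"), di = c(0L, 1L),
    frame_index = 1:2, t_s = c(0, 1),
    x1 = c(0.5, 1), x2 = c(-1, 2), x3 = c(0.2, -0.3), x4 = c(0, 4),
    label = c(TRUE, FALSE))
  dm <- build_design_matrix(df)
  expect_equal(colnames(dm$x),
               c("x1", "x2", "x3", "x4", "DI",
                 "DI.x1", "DI.x2", "DI.x3", "DI.x4"))
  expect_equal(unname(dm$x[1, 5:9]), rep(0, 5))
  expect_equal(unname(dm$x[2, 6:9]), c(1, 2, -0.3, 4))

  beta <- c(0.7, 2.6, -0.2, 0.02, 2.8, -0.1, -1.2, -0.27, -0.33)
  direct <- function(x1, x2, x3, x4, di)
    sum(beta * c(x1, x2, x3, x4, di, di * x1, di * x2, di * x3, di * x4))
  expect_equal(drop(dm$x %*% beta),
               c(direct(0.5, -1, 0.2, 0, 0), direct(1, 2, -0.3, 4, 1)))

  # interaction identity over random frames
  set.seed(2)
  n <- 40
  rdf <- data.frame(dataset_id = "r", modality = "SE",
                    domain = sample(c("phantom", "patient"), n, TRUE),
                    frame_index = 1:n, t_s = 1:n,
                    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                    x4 = rnorm(n), label = TRUE)
  rdf$di <- as.integer(rdf$domain == "patient")
  dmr <- build_design_matrix(rdf)
  for (k in 1:4)
    expect_equal(dmr$x[, 5 + k], dmr$x[, 5] * dmr$x[, k])

  expect_error(build_design_matrix(transform(df, label = NA)), "unlabeled")
})

test_that("band weights follow the scheme with phantom fixed at 1", {
  df <- data.frame(dataset_id = c("ph1", "pA", "pB", "pC"),
                   domain = c("phantom", "patient", "patient", "patient"))
  q <- c(pA = "good", pB = "moderate", pC = "poor")
  w <- assign_weights(df, q)$weight
  expect_equal(w, c(1, 1, 0.6, 0.2))
  w2 <- assign_weights(df, q, weight_scheme(1, 0.5, 0.5))$weight
  expect_equal(w2, c(1, 1, 0.5, 0.5))
  expect_error(assign_weights(df, q[-2]), "band")
  expect_error(weight_scheme(poor = 0), "weights")
  # defaults sit inside the swept grids
  ws <- weight_scheme()
  expect_true(any(abs(ws$moderate - seq(0.4, 0.8, by = 0.1)) < 1e-9))
  expect_true(any(abs(ws$poor - seq(0.1, 0.3, by = 0.05)) < 1e-9))
})
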