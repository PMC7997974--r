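test_that("EOM calibration recovers a known sinusoid and round-trips", {
  truth <- synthetic_eom_calibration(p_max = 80)
  v <- seq(0, 1.2, by = 0.1)
  # noiseless samples from the known sinusoid: parameters recovered and
  # the voltage -> power -> voltage round trip is exact to 1e-6
  cal <- fit_eom_calibration(v, eom_power(truth, v))
  expect_lt(cal$rms, 1e-8)
  vv <- seq(0, 1.2, length.out = 100)
  expect_lt(max(abs(eom_voltage(cal, eom_power(cal, vv)) - vv)), 1e-6)
  # noisy measurements still give a tight, monotone, zero-anchored fit
  set.seed(1)
  cal_n <- fit_eom_calibration(v, eom_power(truth, v) + rnorm(length(v), sd = 1e-4))
  expect_lt(cal_n$rms, 1e-3)
  expect_equal(eom_power(cal_n, 0), 0, tolerance = 1e-12)
  expect_true(all(diff(eom_power(cal_n, vv)) > 0))
  expect_error(fit_eom_calibration(c(0, 0.5, 1.2), c(0, 1, 2)), "4 distinct")
  expect_error(fit_eom_calibration(v, -eom_power(truth, v)), "monoton")
})

test_that("power-space loss is invariant to calibration reparameterization", {
  cal1 <- synthetic_eom_calibration(p_max = 100)
  # same power curve, shifted phase representation
  cal2 <- structure(list(a = cal1$a, w = cal1$w, phi = cal1$phi + 2 * pi,
                         v_max = 1.2, rms = 0), class = "lami_eom")
  v <- seq(0, 1.2, by = 0.05)
  expect_equal(eom_power(cal1, v), eom_power(cal2, v), tolerance = 1e-9)
  loss <- function(cal, pred, target)
    mean((eom_power(cal, pred) - eom_power(cal, target))^2)
  set.seed(2)
  pred <- runif(50, 0, 1.2); target <- runif(50, 0, 1.2)
  expect_equal(loss(cal1, pred, target), loss(cal2, pred, target),
               tolerance = 1e-9)
})

test_that("standardization composed with its inverse is the identity", {
  set.seed(3)
  X <- matrix(rnorm(200 * 15, mean = 5, sd = 3), 200, 15)
  mu <- colMeans(X); sds <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  Xb <- sweep(sweep(Xs, 2, sds, "*"), 2, mu, "+")
  expect_lt(max(abs(Xb - X) / (abs(X) + 1)), 1e-12)
})

test_that("the predictor memorizes a near-duplicated record", {
  cal <- synthetic_eom_calibration(p_max = 100)
  set.seed(4)
  base <- c(500, 110, 110, 0, 0, 0, 0, 0, 12, 0, 0, 0, 0, 0, 0)
  X <- matrix(rep(base, 200), 200, byrow = TRUE) +
    matrix(rnorm(200 * 15, sd = 1e-6), 200)
  colnames(X) <- c("brightness", "field_x", "field_y", paste0("hist_", 1:12))
  v <- rep(0.6, 200)
  fit <- train_predictor(X, v, cal,
                         predictor_config(hidden = 20, dropout = 0,
                                          batch_size = 200, lr = 1e-2,
                                          max_epochs = 400, patience = 50,
                                          val_frac = 0.1))
  pred <- eom_power(cal, lamikit:::nn_predict(
    fit$par, lamikit:::predictor_standardize(fit, X[1:5, , drop = FALSE])))
  expect_lt(max(abs(pred - eom_power(cal, 0.6))), 0.5)
})

test_that("zero-variance feature columns are rejected by name", {
  cal <- synthetic_eom_calibration()
  X <- matrix(rnorm(150 * 3), 150, 3,
              dimnames = list(NULL, c("brightness", "field_x", "field_y")))
  X[, "field_x"] <- 7
  expect_error(train_predictor(X, runif(150, 0, 1), cal), "field_x")
  expect_error(train_predictor(X[1:50, ], runif(50), cal), "100")
})

test_that("trained predictor behaves physically on a flat phantom", {
  fx <- flat_predictor_fixture()
  # identical focal points give identical outputs (deterministic inference)
  p2 <- predict_power(fx$predictor, fx$map,
                      rbind(c(10, 10, 150), c(10, 10, 150)),
                      rbind(c(50, 50), c(50, 50)))
  expect_identical(p2$power[1], p2$power[2])
  # power grows monotonically with depth along a vertical line (the
  # histogram quantizes depth, so consecutive predictions may tie)
  depths <- seq(10, 280, by = 10)
  pw <- predict_power(fx$predictor, fx$map, cbind(8, -6, depths),
                      matrix(110, length(depths), 2))$power
  frac_up <- mean(diff(pw) >= 0)
  expect_gte(frac_up, 0.95)
  expect_gt(pw[length(pw)], 2 * pw[1])
  # raising the target z-score raises predicted power
  p_lo <- predict_power(fx$predictor, fx$map, c(0, 0, 150),
                        c(110, 110), target = -0.5)$power
  p_hi <- predict_power(fx$predictor, fx$map, c(0, 0, 150),
                        c(110, 110), target = 0.5)$power
  expect_gt(p_hi, p_lo)
  # z-score 0 aims for the training-mean brightness (within 15%)
  p0 <- predict_power(fx$predictor, fx$map, c(0, 0, 150),
                      c(110, 110), target = 0)$power
  a <- attenuation_factor(fx$sample, c(0, 0, 150), fx$pupil)
  achieved <- fx$gain * (p0 * a)^2
  expect_lt(abs(achieved - fx$predictor$mu[1]) / fx$predictor$mu[1], 0.15)
})

test_that("pattern prediction yields 64 values with the right structure", {
  fx <- flat_predictor_fixture()
  pat <- predict_grid(fx$predictor, fx$map, fov_origin = c(-110, -110),
                      z = 150)
  expect_s3_class(pat, "lami_pattern")
  expect_equal(dim(unclass(pat)), c(8, 8))
  expect_true(all(pat >= 0 & pat <= 1))
  # flat sample at uniform depth, vignette off: near-uniform pattern
  vals <- as.vector(unclass(pat))
  expect_lt(sd(vals) / mean(vals), 0.05)
  # tilted surface: monotone gradient along the tilt direction (the
  # surface descends along +x, so depth at fixed z -- and hence power --
  # decreases)
  tilt_pts <- expand.grid(x = seq(-400, 400, by = 50),
                          y = seq(-400, 400, by = 50))
  tilt_pts$z <- 0.35 * tilt_pts$x
  tmap <- build_surface(tilt_pts)
  pat_t <- unclass(predict_grid(fx$predictor, tmap,
                                fov_origin = c(-110, -110), z = 180))
  row_means <- rowMeans(pat_t)  # rows map to x
  expect_lt(cor(seq_along(row_means), row_means), -0.9)
  # a field entirely outside the hull fails
  expect_error(predict_grid(fx$predictor, fx$map,
                            fov_origin = c(5000, 5000), z = 150),
               "outside")
})

test_that("inference is fast enough for real-time use", {
  fx <- flat_predictor_fixture()
  n <- 2000
  pts <- cbind(runif(n, -200, 200), runif(n, -200, 200), runif(n, 20, 250))
  el <- system.time(
    predict_power(fx$predictor, fx$map, pts, matrix(110, n, 2)))["elapsed"]
  expect_lt(el / n, 1e-3)  # ~1 ms per focal point amortized
})

test_that("predictor serialization round-trips through JSON", {
  fx <- flat_predictor_fixture()
  path <- tempfile(fileext = ".json")
  write_predictor(fx$predictor, path)
  back <- read_predictor(path)
  pts <- cbind(c(0, 20), c(0, -30), c(100, 200))
  a <- predict_power(fx$predictor, fx$map, pts, matrix(110, 2, 2))
  b <- predict_power(back, fx$map, pts, matrix(110, 2, 2))
  expect_equal(a$power, b$power, tolerance = 1e-8)
  unlink(path)
})
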