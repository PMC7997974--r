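test_that("segmentation finds, splits and rejects candidates as expected", {
  vol <- array(0, c(40, 40, 10))
  vol <- add_blob(vol, c(10, 10, 5), amp = 100)
  vol <- add_blob(vol, c(30, 30, 5), amp = 100)
  regions <- segment_candidates(vol, seg_params(threshold = 5))
  expect_length(regions, 2)
  # dumbbell: two maxima joined by a bridge splits at the waist
  dumb <- array(0, c(50, 30, 8))
  dumb <- add_blob(dumb, c(17, 15, 4), amp = 100, sigma = 2.5)
  dumb <- add_blob(dumb, c(33, 15, 4), amp = 100, sigma = 2.5)
  regions2 <- segment_candidates(dumb, seg_params(threshold = 3, seed_size = 6))
  expect_length(regions2, 2)
  cx <- sort(vapply(regions2, function(r) mean(r$voxels[, 1]), 0))
  expect_lt(abs(cx[1] - 17), 3)
  expect_lt(abs(cx[2] - 33), 3)
  expect_length(segment_candidates(array(0, c(10, 10, 4))), 0)
})

test_that("engineered features compute the documented spectral quantities", {
  nc <- 6
  vol <- array(1, c(8, 8, 4, nc))   # background 1 everywhere
  vox <- as.matrix(expand.grid(x = 3:5, y = 3:5, z = 2:3))
  # channel means (3,1,1,1,1,1): add 2 to channel 1 inside the region
  for (r in seq_len(nrow(vox))) vol[vox[r, 1], vox[r, 2], vox[r, 3], 1] <- 3
  region <- list(id = 1, voxels = vox)
  f <- engineer_features(region, vol, backgrounds = rep(1, nc))
  expect_equal(unname(f[paste0("spec_", 1:6)]), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(f["magnitude"]), 2)
  expect_equal(unname(f["zero_flag"]), 0)
  # a region identical in two channels: correlation 1, COM distance 0
  vol2 <- array(0, c(8, 8, 4, 2))
  for (r in seq_len(nrow(vox))) {
    v <- runif(1, 1, 5)
    vol2[vox[r, 1], vox[r, 2], vox[r, 3], 1] <- v
    vol2[vox[r, 1], vox[r, 2], vox[r, 3], 2] <- v
  }
  f2 <- engineer_features(region, vol2, backgrounds = c(0, 0))
  expect_equal(unname(f2["cor_1_2"]), 1)
  expect_equal(unname(f2["com_d_1_2"]), 0)
  # zero spectrum after background subtraction sets the flag
  f3 <- engineer_features(region, array(1, c(8, 8, 4, 2)),
                          backgrounds = c(1, 1))
  expect_equal(unname(f3["zero_flag"]), 1)
  expect_true(all(f3[c("spec_1", "spec_2")] == 0))
})

test_that("inter-channel COM distance recovers a built-in fluorophore offset", {
  vol <- array(0, c(40, 40, 12, 2))
  v1 <- add_blob(array(0, c(40, 40, 12)), c(18, 20, 6), amp = 100)
  v2 <- add_blob(array(0, c(40, 40, 12)), c(22, 20, 6), amp = 100)  # +4 um in x
  vol[, , , 1] <- v1; vol[, , , 2] <- v2
  mask <- (v1 + v2) > 5
  vox <- which(mask, arr.ind = TRUE)
  colnames(vox) <- NULL
  region <- list(id = 1, voxels = vox)
  f <- engineer_features(region, vol, backgrounds = c(0, 0))
  expect_lt(abs(f["com_d_1_2"] - 4), 1)   # voxel quantization allowance
  # correlations bounded
  expect_true(all(abs(f[startsWith(names(f), "cor_")]) <= 1))
})

# brute-force normalized-cut oracle over all 2-partitions of a small graph
brute_ncut <- function(w) {
  n <- nrow(w)
  best <- NULL; best_val <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    s <- as.logical(bitwAnd(code, 2^(0:(n - 1))) > 0)
    cut <- sum(w[s, !s])
    assoc1 <- sum(w[s, ]); assoc2 <- sum(w[!s, ])
    val <- cut / assoc1 + cut / assoc2
    if (val < best_val) { best_val <- val; best <- s }
  }
  best
}

test_that("NC-ROI isolates the reference blob, matching the brute-force cut", {
  # two 5-voxel blobs 10 um apart with orthogonal spectra
  vol <- array(0, c(30, 10, 3, 2))
  vox_a <- cbind(8:12, 5, 2)
  vox_b <- cbind(18:22, 5, 2)
  for (r in 1:5) vol[vox_a[r, 1], 5, 2, 1] <- 10
  for (r in 1:5) vol[vox_b[r, 1], 5, 2, 2] <- 10
  region <- list(id = 1, voxels = rbind(vox_a, vox_b))
  cfg <- nc_config(alpha = 0.01, beta = 5, clusters = 2)
  roi <- nc_roi(region, vol, reference = c(1, 0), config = cfg)
  expect_equal(roi$voxels[order(roi$voxels[, 1]), ], vox_a)
  # the spectral partition agrees with exhaustive normalized-cut search
  n <- 10
  s <- rbind(matrix(c(1, 0), 5, 2, byrow = TRUE),
             matrix(c(0, 1), 5, 2, byrow = TRUE))
  um <- rbind(vox_a, vox_b)
  d <- cfg$alpha * as.matrix(dist(um))^2 + cfg$beta * (1 - s %*% t(s))
  w <- exp(-d)
  oracle <- brute_ncut(w)
  expect_true(all(roi$members == oracle) || all(roi$members == !oracle))
})

test_that("NC-ROI degenerate and invariance properties hold", {
  # uniform spectrum: both sides match the reference equally; the union is
  # the full region and the tie goes to the larger side
  vol <- array(0, c(20, 6, 3, 2))
  vox <- cbind(5:15, 3, 2)
  for (r in seq_len(nrow(vox))) vol[vox[r, 1], 3, 2, ] <- c(5, 5)
  region <- list(id = 1, voxels = vox)
  roi <- nc_roi(region, vol, reference = c(1, 1) / sqrt(2))
  expect_gte(nrow(roi$voxels), ceiling(nrow(vox) / 2))
  expect_equal(sort(unique(roi$cluster)), 1:2)
  # global intensity rescaling leaves the partition unchanged
  roi2 <- nc_roi(region, vol * 7, reference = c(1, 1) / sqrt(2))
  expect_equal(roi$members, roi2$members)
  expect_error(nc_roi(list(id = 1, voxels = vox[1, , drop = FALSE]), vol,
                      c(1, 0)), "fewer voxels")
})

test_that("alpha = 0 makes the cut depend on spectra alone", {
  vol <- array(0, c(30, 10, 3, 2))
  vox <- cbind(c(3, 9, 15, 21, 27, 5, 11, 17, 23, 29), 5, 2)
  spectra <- rep(c(1, 2), each = 5)
  for (r in 1:10)
    vol[vox[r, 1], 5, 2, spectra[r]] <- 8
  region <- list(id = 1, voxels = vox)
  roi <- nc_roi(region, vol, reference = c(1, 0),
                config = nc_config(alpha = 0, beta = 5))
  expect_equal(sort(roi$voxels[, 1]), sort(vox[spectra == 1, 1]))
})

test_that("classifier ensemble separates, averages and calibrates sensibly", {
  set.seed(11)
  X <- rbind(matrix(rnorm(60, mean = 3), 30, 2),
             matrix(rnorm(60, mean = -3), 30, 2))
  y <- rep(c(1, 0), each = 30)
  ens <- train_classifier(X, y, members = 3, seed = 2)
  Xt <- rbind(matrix(rnorm(40, mean = 3), 20, 2),
              matrix(rnorm(40, mean = -3), 20, 2))
  yt <- rep(c(1, 0), each = 20)
  acc <- mean((predict_ensemble(ens, Xt) > 0.5) == yt)
  expect_equal(acc, 1)
  expect_error(train_classifier(X, rep(1, 60)), "each class")
  # duplicate rows with conflicting labels score near 0.5
  Xc <- matrix(rep(c(0.5, 0.5), 40), 40, 2, byrow = TRUE) +
    matrix(rnorm(80, sd = 1e-3), 40, 2)
  yc <- rep(c(0, 1), 20)
  ens_c <- train_classifier(Xc, yc, members = 3, seed = 3)
  sc <- predict_ensemble(ens_c, matrix(c(0.5, 0.5), 1, 2))
  expect_gt(sc, 0.25); expect_lt(sc, 0.75)
  # a single-member ensemble is its own mean
  e1 <- train_classifier(X, y, members = 1, seed = 4)
  expect_equal(predict_ensemble(e1, Xt),
               1 / (1 + exp(-lamikit:::nn_predict(
                 e1$nets[[1]],
                 sweep(sweep(Xt, 2, e1$mu), 2, e1$sd, "/")))))
})

test_that("uncertainty sampling selects the score closest to 0.5", {
  set.seed(12)
  X <- rbind(matrix(rnorm(40, 3), 20, 2), matrix(rnorm(40, -3), 20, 2))
  y <- rep(c(1, 0), each = 20)
  ens <- train_classifier(X, y, members = 1, seed = 5)
  pool <- rbind(c(3, 3), c(0.05, 0.02), c(-3, -3))
  sc <- predict_ensemble(ens, pool)
  expect_equal(uncertainty_select(ens, pool), which.min(abs(sc - 0.5)))
  expect_equal(uncertainty_select(ens, pool[2, , drop = FALSE]), 1L)
  expect_error(uncertainty_select(ens, pool[0, , drop = FALSE]), "empty")
})

test_that("active learning reaches full accuracy cheaply on a separable pool", {
  set.seed(13)
  n <- 400
  X <- rbind(matrix(rnorm(2 * 40, mean = 4), 40, 2),
             matrix(rnorm(2 * (n - 40), mean = -1), n - 40, 2))
  y <- c(rep(1, 40), rep(0, n - 40))
  curve <- simulate_labeling_experiment(X, y, "uncertainty", budget = 40,
                                        eval_every = 2, seed = 1)
  reached <- curve$labels[which(curve$balanced_accuracy >= 0.999)[1]]
  expect_false(is.na(reached))
  expect_lte(reached, 0.1 * n)
})
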