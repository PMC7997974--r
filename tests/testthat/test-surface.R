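test_that("piecewise-linear surface reproduces inputs and is undefined outside", {
  pts <- data.frame(x = c(0, 100, 0, 100, 50), y = c(0, 0, 100, 100, 50),
                    z = 20)
  map <- build_surface(pts)
  expect_equal(surface_z(map, c(10, 80), c(10, 60)), c(20, 20))
  expect_true(is.na(surface_z(map, 500, 500)))
  expect_true(is.na(surface_z(map, 500, 500, exact = TRUE)))
  # exact at input points
  expect_equal(surface_z(map, pts$x, pts$y, exact = TRUE), pts$z)
  expect_error(build_surface(data.frame(x = 1:5, y = 2 * (1:5), z = 0)),
               "collinear")
})

test_that("sphere-cap interpolation error respects the chord-sagitta bound", {
  R <- 510
  sp <- make_sample("sphere", ls = 100, center = c(0, 0, R), radius = R)
  h <- 20
  pts <- sample_surface_points(sp, spacing = h)
  keep <- sqrt(pts$x^2 + pts$y^2) < R * sin(pi / 6)  # 30 degree cap
  map <- build_surface(pts[keep, ])
  set.seed(1)
  qx <- runif(300, -100, 100); qy <- runif(300, -100, 100)
  z_true <- sample_surface_height(sp, qx, qy)
  z_pwl <- surface_z(map, qx, qy, exact = TRUE)
  ok <- !is.na(z_pwl)
  # max |Hessian| on a 30-degree cap is 1/(R cos^3 30), PWL error <= M h^2 / 8
  # with the triangle diameter ~ sqrt(2) h for the hexagonal sampling
  bound <- (sqrt(2) * h)^2 / (8 * R * cos(pi / 6)^3)
  expect_lt(max(abs(z_pwl[ok] - z_true[ok])), bound * 1.05)
})

test_that("ray distance search matches closed forms on a flat surface", {
  map <- flat_map()
  cfg <- shape_config()
  d_vert <- distance_to_surface(map, c(0, 0, 100), matrix(c(0, 0, -1), 1), cfg)
  expect_lt(abs(d_vert - 100), cfg$search_tol + 1e-9)
  phi <- 20 * pi / 180
  u <- matrix(c(sin(phi), 0, -cos(phi)), 1)
  d_inc <- distance_to_surface(map, c(0, 0, 100), u, cfg)
  expect_lt(abs(d_inc - 100 / cos(phi)), cfg$search_tol + 1e-9)
  # binary search converges within ceil(log2(start / tol)) halvings
  expect_identical(ceiling(log2(cfg$search_start / cfg$search_tol)), 11)
})

test_that("ray distances match the analytic sphere-line intersection", {
  fx <- sphere_fixture(spacing = 10)
  cfg <- shape_config()
  set.seed(2)
  for (k in 1:10) {
    p <- c(runif(1, -100, 100), runif(1, -100, 100), runif(1, 50, 300))
    th <- runif(1, 0, 0.5); ps <- runif(1, 0, 2 * pi)
    u <- matrix(c(sin(th) * cos(ps), sin(th) * sin(ps), -cos(th)), 1)
    d_num <- distance_to_surface(fx$map, p, u, cfg)
    dp <- p - c(0, 0, 510)
    b <- sum(dp * u); c0 <- sum(dp^2) - 510^2
    d_an <- -b + sqrt(b^2 - c0)
    expect_lt(abs(d_num - d_an), 2.5)  # search tol + PWL facet error
  }
})

test_that("rays that never cross are flagged at the search start", {
  map <- flat_map(extent = 3000, spacing = 300)
  cfg <- shape_config(search_start = 200)
  # very oblique ray from deep down cannot reach the surface within 200 um
  u <- matrix(c(sin(1.4), 0, -cos(1.4)), 1)
  d <- suppressWarnings(distance_to_surface(map, c(0, 0, 150), u, cfg))
  expect_equal(as.numeric(d), 200)
  expect_true(attr(d, "no_crossing"))
})

test_that("histogram bins follow the power-law edges and sum to n_rays", {
  cfg <- shape_config()
  edges <- shape_bin_edges(cfg)
  expect_length(edges, 13)
  expect_identical(max(edges), 350)
  expect_equal(edges, (seq(0, 1, length.out = 13))^1.5 * 350)
  map <- flat_map()
  # focal point on the surface: every distance ~ 0 -> first bin
  h0 <- suppressWarnings(shape_histogram(map, c(0, 0, 0.2), cfg))
  expect_equal(h0[1, 1], 12L)
  expect_equal(sum(h0), 12L)
  # depth chosen so all 12 distances are 100 um -> the 94.1-123.7 bin
  depth <- 100 * cos(20 * pi / 180)
  h1 <- shape_histogram(map, c(0, 0, depth), cfg)
  expect_equal(h1[1, 6], 12L)
  # distances beyond d_max clamp into the last bin, preserving the sum
  h2 <- shape_histogram(map, c(0, 0, 340), cfg)
  expect_equal(sum(h2), 12L)
  expect_equal(h2[1, 12], 12L)
})

test_that("histogram is invariant to azimuthal phase over symmetric surfaces", {
  map <- flat_map()
  cfg <- shape_config()
  p <- c(15, -22, 130)
  h_a <- shape_histogram(map, p, cfg, phase = 0)
  h_b <- shape_histogram(map, p, cfg, phase = 0.7)
  expect_identical(h_a, h_b)
})

test_that("feature vectors have the documented layout and symmetry", {
  map <- flat_map()
  f <- featurize(map, c(0, 0, 120), brightness = 55, field_xy = c(30, 40))
  expect_length(f, 15)
  expect_named(f, c("brightness", "field_x", "field_y",
                    paste0("hist_", 1:12)))
  expect_equal(unname(f[1:3]), c(55, 30, 40))
  # mirrored azimuths over a flat surface differ only in field position
  f2 <- featurize(map, c(0, 0, 120), brightness = 55, field_xy = c(180, 40))
  expect_equal(f[-(2:3)], f2[-(2:3)])
})

test_that("deeper vertical focus never shortens any ray distance", {
  map <- flat_map()
  cfg <- shape_config()
  u <- lamikit:::shape_ray_directions(cfg)
  d_shallow <- distance_to_surface(map, matrix(rep(c(5, 5, 60), 12),
                                               ncol = 3, byrow = TRUE), u, cfg)
  d_deep <- distance_to_surface(map, matrix(rep(c(5, 5, 180), 12),
                                            ncol = 3, byrow = TRUE), u, cfg)
  expect_true(all(d_deep >= d_shallow - cfg$search_tol))
})

test_that("feature extraction is fast enough for acquisition-scale batches", {
  fx <- sphere_fixture(spacing = 20)
  cands <- seed_candles(fx$sample, 1e4, seed = 3)
  elapsed <- system.time({
    X <- suppressWarnings(
      featurize_points(fx$map, as.matrix(cands[, c("x", "y", "z")]),
                       cands$b, matrix(50, nrow(cands), 2)))
  })["elapsed"]
  expect_equal(dim(X), c(1e4, 15))
  expect_lt(elapsed, 60)
})
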