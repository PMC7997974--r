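test_that("sample geometries answer inside/outside and surface queries", {
  sp <- make_sample("sphere", ls = 100, center = c(0, 0, 510), radius = 510)
  expect_true(sample_inside(sp, c(0, 0, 510)))
  expect_false(sample_inside(sp, c(0, 0, 510 + 511)))

  fl <- make_sample("flat", ls = 50, z_top = 0)
  xs <- seq(-300, 300, by = 50)
  expect_true(all(sample_surface_height(fl, xs, xs) == 0))

  # two-lobe union: the surface has a local maximum (minimum z) at each apex
  tl <- make_sample("two_lobe", ls = 100,
                    lobes = list(list(center = c(-150, 0, 200), radius = 180),
                                 list(center = c(150, 0, 230), radius = 200)))
  xs <- seq(-300, 320, by = 5)
  z <- sample_surface_height(tl, xs, rep(0, length(xs)))
  interior <- which(!is.na(z))
  zi <- z[interior]
  local_min <- which(diff(sign(diff(zi))) > 0) + 1  # minima of z = apices
  expect_length(local_min, 2)
  apex_x <- xs[interior][local_min]
  expect_lt(abs(apex_x[1] - (-150)), 10)
  expect_lt(abs(apex_x[2] - 150), 10)
})

test_that("degenerate sample specifications are rejected", {
  expect_error(make_sample("sphere", ls = -5), "mean free path")
  expect_error(make_sample("sphere", radius = 0), "radius")
  expect_error(make_sample("ellipsoid", semiaxes = c(100, 0, 50)), "semi-axes")
  expect_error(make_sample("two_lobe"), "lobes")
})

test_that("seeded candles have the specified brightness statistics", {
  sp <- make_sample("sphere", ls = 100, center = c(0, 0, 510), radius = 510)
  c0 <- seed_candles(sp, 1000, brightness_cv = 0, seed = 3)
  expect_true(all(c0$b == 1))
  c1 <- seed_candles(sp, 1e4, brightness_cv = 0.2, seed = 4)
  expect_gt(mean(c1$b), 0.98)
  expect_lt(mean(c1$b), 1.02)
  # positions inside the sample, within the depth window
  expect_true(all(sample_inside(sp, as.matrix(c1[, c("x", "y", "z")]))))
  depth <- c1$z - sample_surface_height(sp, c1$x, c1$y)
  expect_true(all(depth > 0 & depth <= 300))
  # determinism
  c2 <- seed_candles(sp, 50, brightness_cv = 0.2, seed = 9)
  c3 <- seed_candles(sp, 50, brightness_cv = 0.2, seed = 9)
  expect_identical(c2, c3)
})

test_that("attenuation follows the per-ray exponential law", {
  fl <- make_sample("flat", ls = 100)
  # no scattering or zero depth leaves the excitation untouched
  expect_equal(attenuation_factor(fl, c(0, 0, 100), paraxial_pupil(),
                                  ls = Inf), 1)
  expect_equal(attenuation_factor(fl, c(0, 0, 1e-9), paraxial_pupil()), 1,
               tolerance = 1e-8)
  # single axial ray at depth ls
  expect_equal(attenuation_factor(fl, c(0, 0, 100), paraxial_pupil()),
               exp(-1), tolerance = 1e-12)
  sp <- make_sample("sphere", ls = 100, center = c(0, 0, 510), radius = 510)
  expect_error(attenuation_factor(sp, c(0, 0, 2000)), "inside")
})

test_that("quadrature attenuation matches Monte-Carlo ray sampling", {
  sp <- make_sample("sphere", ls = 100, center = c(0, 0, 510), radius = 510)
  set.seed(42)
  for (k in 1:5) {
    p <- c(runif(1, -150, 150), runif(1, -150, 150), runif(1, 30, 300))
    aq <- attenuation_factor(sp, p)
    am <- attenuation_factor_mc(sp, p, n_rays = 5e4, seed = k)
    expect_lt(abs(aq - am) / aq, 0.01)
  }
})

test_that("attenuation decreases monotonically with depth in a convex sample", {
  sp <- make_sample("sphere", ls = 120, center = c(0, 0, 510), radius = 510)
  depths <- seq(5, 400, by = 20)
  a <- attenuation_factor(sp, cbind(40, -30,
                                    sample_surface_height(sp, 40, -30) + depths))
  expect_true(all(diff(a) < 0))
})

test_that("sphere requires no more power than a flat sample at equal depth", {
  ls <- 100
  sp <- make_sample("sphere", ls = ls, center = c(0, 0, 510), radius = 510)
  fl <- make_sample("flat", ls = ls)
  pup <- pupil_model()
  depths <- c(50, 150, 250)
  p_sphere <- relative_power(sp, cbind(0, 0, depths), pup)
  p_flat <- relative_power(fl, cbind(0, 0, depths), pup)
  expect_true(all(p_sphere <= p_flat + 1e-9))
})

test_that("simulated brightness obeys the two-photon square law", {
  fl <- make_sample("flat", ls = 100, vignette_strength = 0)
  grid <- acquisition_grid(n_tiles = c(2, 2))
  cands <- data.frame(id = 1:2, x = c(0, 0), y = c(0, 0), z = c(1e-6, 120),
                      b = 1)
  run <- function(p0) {
    simulate_acquisition(fl, cands, grid, function(pts) rep(p0, nrow(pts)),
                         paraxial_pupil(), randomize = c(1, 1),
                         shot_noise = FALSE, seed = 1)
  }
  r1 <- run(2); r2 <- run(4)
  expect_equal(r2$brightness, 4 * r1$brightness, tolerance = 1e-12)
  # depth dependence at constant power: F(z)/F(0) = exp(-2 z / ls)
  expect_equal(r1$brightness[2] / r1$brightness[1], exp(-2 * 120 / 100),
               tolerance = 1e-6)
})

test_that("per-tile randomizing factors stay within the stated range", {
  sp <- make_sample("sphere", ls = 100, center = c(0, 0, 510), radius = 510)
  grid <- acquisition_grid()
  cands <- seed_candles(sp, 3000, brightness_cv = 0, seed = 5)
  rec <- suppressWarnings(
    simulate_acquisition(sp, cands, grid, function(pts) rep(3, nrow(pts)),
                         pupil_model(n_theta = 8, n_phi = 8),
                         shot_noise = FALSE, seed = 6))
  u <- rec$P0 / 3
  expect_gte(min(u), 0.5)
  expect_lte(max(u), 2)
  # many tiles explore most of the range
  expect_lt(min(u), 0.8)
  expect_gt(max(u), 1.6)
  expect_error(
    simulate_acquisition(sp, cands[1:5, ], grid,
                         function(pts) rep(-1, nrow(pts)), pupil_model()),
    "negative")
})

test_that("identical seeds give bit-identical simulated records", {
  sp <- make_sample("sphere", ls = 100, center = c(0, 0, 510), radius = 510)
  grid <- acquisition_grid()
  cands <- seed_candles(sp, 100, seed = 7)
  pol <- function(pts) rep(2, nrow(pts))
  r1 <- simulate_acquisition(sp, cands, grid, pol,
                             pupil_model(n_theta = 6, n_phi = 6), seed = 8)
  r2 <- simulate_acquisition(sp, cands, grid, pol,
                             pupil_model(n_theta = 6, n_phi = 6), seed = 8)
  expect_identical(r1, r2)
})

test_that("rank denoising rejects single-scan outliers, keeps constants", {
  const <- matrix(7, 20, 20)
  expect_equal(rank_denoise(const, const, gaussian_sigma = 0), const)
  # saturated pixel present in one scan only
  hot <- const
  hot[10, 10] <- 1000
  den <- rank_denoise(const, hot, gaussian_sigma = 0)
  expect_lt(den[10, 10], 0.5 * 1000)
  expect_error(rank_denoise(matrix(0, 4, 4), matrix(0, 5, 5)), "shape")
})

test_that("the Gaussian stage suppresses i.i.d. noise variance by >= 4x", {
  set.seed(10)
  a <- matrix(rnorm(96 * 96), 96, 96)
  sm <- gauss_smooth(a, 2)
  inner <- sm[20:77, 20:77]
  expect_lt(var(as.vector(inner)), var(as.vector(a)) / 4)
})

test_that("rendered tiles contain candle blobs and a surface band", {
  fl <- make_sample("flat", ls = 100)
  grid <- acquisition_grid(pixels = 32, n_tiles = c(2, 2))
  scale <- grid$fov / grid$pixels
  rec <- data.frame(candle_id = 1, x = grid$origin[1] + 15.5 * scale,
                    y = grid$origin[2] + 15.5 * scale, z = 60,
                    tile_x = 0, tile_y = 0, brightness = 500)
  vol <- render_tile(fl, rec, grid, tile = c(0, 0))
  expect_length(dim(vol), 4)
  expect_equal(dim(vol)[c(1, 2, 4)], c(32, 32, 2))
  # candle channel has a bright blob at the right plane
  expect_gt(max(vol[, , , 1]), 100)
  zmax <- which.max(apply(vol[, , , 1], 3, max))
  expect_equal(zmax, which.min(abs(seq(0, 120, by = 4) - 60)))
  # SHG channel peaks at the (flat) surface plane
  shg_profile <- apply(vol[, , , 2], 3, max)
  expect_identical(which.max(shg_profile), 1L)
})
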