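# Shared fixture builders. Everything is generated in code at test time.

flat_map <- function(extent = 800, spacing = 100, z0 = 0) {
  s <- make_sample("flat", ls = 100, z_top = z0, extent = extent)
  build_surface(sample_surface_points(s, spacing = spacing))
}

sphere_fixture <- function(ls = 100, radius = 510, spacing = 15) {
  s <- make_sample("sphere", ls = ls, center = c(0, 0, radius),
                   radius = radius)
  list(sample = s, map = build_surface(sample_surface_points(s, spacing = spacing)))
}

# small multi-channel test stack with bright blobs and (optionally) a
# z-correlated fine background texture, like tissue autofluorescence:
# sharp in XY (registration signal) but smooth across planes
blob_volume <- function(dim = c(48, 48, 12), n_blobs = 6, sigma = 1.5,
                        channels = 1, seed = 1, background = 0,
                        texture_amp = 0) {
  set.seed(seed)
  vol <- array(background, c(dim, channels))
  if (texture_amp > 0) {
    # fine in XY, long-range in z: adjacent 4-um planes of real stacks are
    # highly correlated
    tex <- gauss_smooth(array(rnorm(prod(dim)), dim), c(1, 1, 4))
    tex <- texture_amp * tex / sd(tex)
    for (ch in seq_len(channels)) vol[, , , ch] <- vol[, , , ch] + tex
  }
  xs <- seq_len(dim[1]); ys <- seq_len(dim[2]); zs <- seq_len(dim[3])
  for (b in seq_len(n_blobs)) {
    c0 <- c(runif(1, 8, dim[1] - 8), runif(1, 8, dim[2] - 8),
            runif(1, 3, dim[3] - 3))
    amp <- runif(1, 50, 150)
    gx <- exp(-(xs - c0[1])^2 / (2 * sigma^2))
    gy <- exp(-(ys - c0[2])^2 / (2 * sigma^2))
    gz <- exp(-(zs - c0[3])^2 / (2 * sigma^2))
    for (ch in seq_len(channels))
      vol[, , , ch] <- vol[, , , ch] + amp * (gx %o% gy %o% gz)
  }
  if (channels == 1) array(vol, dim) else vol
}

# place a Gaussian blob at a voxel position in a single-channel volume
add_blob <- function(vol, center, amp = 100, sigma = 1.5) {
  d <- dim(vol)
  gx <- exp(-(seq_len(d[1]) - center[1])^2 / (2 * sigma^2))
  gy <- exp(-(seq_len(d[2]) - center[2])^2 / (2 * sigma^2))
  gz <- exp(-(seq_len(d[3]) - center[3])^2 / (2 * sigma^2))
  vol + amp * (gx %o% gy %o% gz)
}

# cheap flat-phantom predictor shared across powernet tests
local_predictor_cache <- new.env(parent = emptyenv())
flat_predictor_fixture <- function() {
  if (!is.null(local_predictor_cache$fit)) return(local_predictor_cache$fit)
  s <- make_sample("flat", ls = 100, extent = 800, vignette_strength = 0)
  map <- flat_map()
  grid <- acquisition_grid(n_tiles = c(4, 4))
  cands <- seed_candles(s, 2500, brightness_cv = 0.1, max_depth = 320,
                        seed = 11)
  pup <- paraxial_pupil()
  policy <- function(pts) {
    1 / attenuation_factor(s, pts, pup)
  }
  rec <- suppressWarnings(simulate_acquisition(s, cands, grid, policy, pup,
                                               gain = 400, seed = 12))
  cal <- synthetic_eom_calibration(p_max = 100)
  ts <- suppressWarnings(candle_training_set(map, rec, cal))
  fit <- train_predictor(ts$X, ts$voltage, cal,
                         predictor_config(hidden = 100, lr = 3e-3,
                                          max_epochs = 1200, patience = 40,
                                          lr_decays = 3, seed = 5))
  out <- list(predictor = fit, map = map, sample = s, grid = grid,
              cal = cal, pupil = pup, gain = 400)
  local_predictor_cache$fit <- out
  out
}
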