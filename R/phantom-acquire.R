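#' Acquisition grid description
#'
#' Tiled raster-scan geometry: square XY fields of view of size `fov`
#' covering the sample with fractional `overlap`, planes every `z_step`.
#'
#' @param fov XY field size (um).
#' @param pixels pixels per side of a field.
#' @param z_step spacing between successive planes (um), > 0.
#' @param n_tiles tiles in x and y (length-2 integer).
#' @param overlap tile overlap fraction in [0, 0.5).
#' @param origin XY position of the corner of tile (1,1) (um).
#' @param channels number of detection channels.
#' @return object of class `lami_grid`.
#' @export
acquisition_grid <- function(fov = 220, pixels = 64, z_step = 4,
                             n_tiles = c(6, 6), overlap = 0.1,
                             origin = NULL, channels = 2) {
  if (z_step <= 0) stop("z_step must be > 0")
  if (overlap < 0 || overlap >= 0.5) stop("overlap fraction must lie in [0, 0.5)")
  pitch <- fov * (1 - overlap)
  if (is.null(origin)) {
    span <- pitch * (n_tiles - 1) + fov
    origin <- -span / 2
  }
  structure(list(fov = fov, pixels = pixels, z_step = z_step,
                 n_tiles = n_tiles, overlap = overlap, pitch = pitch,
                 origin = origin, channels = channels),
            class = "lami_grid")
}

# tile indices (0-based) and in-field positions for absolute XY coordinates
locate_in_grid <- function(grid, x, y) {
  ti <- clamp(floor((x - grid$origin[1]) / grid$pitch), 0, grid$n_tiles[1] - 1)
  tj <- clamp(floor((y - grid$origin[2]) / grid$pitch), 0, grid$n_tiles[2] - 1)
  fx <- clamp(x - (grid$origin[1] + ti * grid$pitch), 0, grid$fov)
  fy <- clamp(y - (grid$origin[2] + tj * grid$pitch), 0, grid$fov)
  list(tile_x = ti, tile_y = tj, field_x = fx, field_y = fy)
}

#' Simulate a standard-candle calibration acquisition
#'
#' Images each candle with power `P0 = power_policy(position) * u(tile)`,
#' where `u` is a per-tile randomizing factor drawn uniformly from
#' `randomize`. The noiseless expected brightness follows the two-photon
#' law `F = gain * b * vignette(x, y) * (P0 * A)^2`, with `A` the
#' pupil-averaged attenuation at the candle position; optional Poisson shot
#' noise is applied on the photon count `F * photons_per_unit`.
#'
#' @param sample a `lami_sample`.
#' @param candles data.frame from [seed_candles()].
#' @param grid a `lami_grid`.
#' @param power_policy function mapping an n x 3 position matrix to
#'   non-negative base powers (relative units).
#' @param pupil a `lami_pupil`.
#' @param gain detector gain (brightness units per photon-law unit).
#' @param randomize range of the per-tile uniform randomizing factor; use
#'   `c(1, 1)` to disable.
#' @param shot_noise apply Poisson noise to the measured brightness.
#' @param photons_per_unit photons corresponding to one brightness unit.
#' @param read_noise_sd Gaussian detector read noise (brightness units),
#'   off by default.
#' @param seed RNG seed.
#' @return data.frame of simulated records: `candle_id`, absolute position,
#'   tile indices, field position, applied power `P0`, attenuation `A`, and
#'   measured `brightness`.
#' @export
simulate_acquisition <- function(sample, candles, grid, power_policy,
                                 pupil = pupil_model(), gain = 1,
                                 randomize = c(0.5, 2), shot_noise = TRUE,
                                 photons_per_unit = 1, read_noise_sd = 0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- as.matrix(candles[, c("x", "y", "z")])
  base <- power_policy(pos)
  if (any(base < 0)) stop("power_policy returned negative power")
  loc <- locate_in_grid(grid, candles$x, candles$y)
  tile_id <- loc$tile_x * grid$n_tiles[2] + loc$tile_y
  u_tiles <- stats::runif(prod(grid$n_tiles), randomize[1], randomize[2])
  P0 <- base * u_tiles[tile_id + 1L]
  A <- attenuation_factor(sample, pos, pupil)
  vig <- vignette_at(sample, loc$field_x, loc$field_y)
  F_exp <- gain * candles$b * vig * (P0 * A)^2
  brightness <- if (shot_noise)
    stats::rpois(length(F_exp), F_exp * photons_per_unit) / photons_per_unit
  else F_exp
  if (read_noise_sd > 0)
    brightness <- pmax(brightness +
                         stats::rnorm(length(brightness), sd = read_noise_sd), 0)
  data.frame(candle_id = candles$id, x = candles$x, y = candles$y,
             z = candles$z, tile_x = loc$tile_x, tile_y = loc$tile_y,
             field_x = loc$field_x, field_y = loc$field_y,
             P0 = P0, attenuation = A, expected = F_exp,
             brightness = brightness)
}

#' Render one tile of a simulated acquisition as an image stack
#'
#' Produces a `pixels x pixels x planes x channels` array: channel 1 holds
#' the candles as 3D Gaussian blobs (amplitude = their simulated
#' brightness) on a dark background, channel 2 an SHG-like band at the
#' sample surface.
#'
#' @param sample a `lami_sample`.
#' @param records records from [simulate_acquisition()] (or any data.frame
#'   with `x`, `y`, `z`, `brightness`, `tile_x`, `tile_y`).
#' @param grid a `lami_grid`.
#' @param tile 0-based tile indices `c(i, j)`.
#' @param z_planes z positions of the planes (um); default spans the tile's
#'   surface down `depth_range` um.
#' @param blob_sigma candle blob standard deviation (um).
#' @param depth_range rendered depth below the shallowest surface (um).
#' @param background dark-count offset added everywhere.
#' @return 4D numeric array (x, y, z, channel).
#' @export
render_tile <- function(sample, records, grid, tile = c(0, 0),
                        z_planes = NULL, blob_sigma = 2,
                        depth_range = 120, background = 1) {
  px <- grid$pixels
  scale <- grid$fov / px
  x0 <- grid$origin[1] + tile[1] * grid$pitch
  y0 <- grid$origin[2] + tile[2] * grid$pitch
  xc <- x0 + (seq_len(px) - 0.5) * scale
  yc <- y0 + (seq_len(px) - 0.5) * scale
  if (is.null(z_planes)) {
    tops <- sample_surface_height(sample, rep(xc, times = px), rep(yc, each = px))
    zmin <- min(tops, na.rm = TRUE)
    z_planes <- seq(zmin, zmin + depth_range, by = grid$z_step)
  }
  nz <- length(z_planes)
  vol <- array(background, c(px, px, nz, 2))
  rec <- records[records$tile_x == tile[1] & records$tile_y == tile[2], ,
                 drop = FALSE]
  s2 <- blob_sigma^2
  for (k in seq_len(nrow(rec))) {
    gx <- exp(-(xc - rec$x[k])^2 / (2 * s2))
    gy <- exp(-(yc - rec$y[k])^2 / (2 * s2))
    gz <- exp(-(z_planes - rec$z[k])^2 / (2 * s2))
    keep <- gz > 1e-4
    if (!any(keep)) next
    blob <- outer(gx, gy) %o% gz[keep]
    vol[, , keep, 1] <- vol[, , keep, 1] + rec$brightness[k] * blob
  }
  # SHG-like surface band
  top <- matrix(sample_surface_height(sample, rep(xc, times = px),
                                      rep(yc, each = px)),
                px, px, byrow = TRUE)
  for (iz in seq_len(nz)) {
    band <- exp(-(z_planes[iz] - top)^2 / (2 * (2 * blob_sigma)^2))
    band[is.na(band)] <- 0
    vol[, , iz, 2] <- vol[, , iz, 2] + 50 * band
  }
  vol
}

# shifted copy of a matrix with edge replication
shift_clamp2d <- function(m, dx, dy) {
  d <- dim(m)
  ix <- clamp(seq_len(d[1]) - dx, 1L, d[1])
  iy <- clamp(seq_len(d[2]) - dy, 1L, d[2])
  m[ix, iy, drop = FALSE]
}

#' Rank-filter denoising of repeated scans
#'
#' Simplified spatiotemporal rank filtering: two repeated scans of each
#' plane are pooled, and every output pixel is the median of the 2 x 9
#' samples in the 3 x 3 neighbourhoods of both scans (edge-replicated), so
#' isolated single-scan outliers are rejected while constant regions pass
#' through unchanged. A 2D Gaussian (`gaussian_sigma` pixels) is then
#' applied to each plane; set `gaussian_sigma = 0` to inspect the rank
#' stage alone.
#'
#' @param scan1,scan2 matrices (one plane) or 3D arrays (planes stacked on
#'   the third margin) of identical shape.
#' @param window odd spatial window size (3 = 3 x 3 neighbourhood).
#' @param gaussian_sigma sigma of the post-filter Gaussian (pixels).
#' @return denoised array shaped like the input.
#' @export
rank_denoise <- function(scan1, scan2, window = 3, gaussian_sigma = 2) {
  if (!identical(dim(scan1), dim(scan2)))
    stop("the two scans must have identical shapes")
  one_plane <- function(a, b) {
    r <- (window - 1L) / 2L
    stack <- vector("list", 2L * window^2)
    k <- 0L
    for (dx in -r:r) for (dy in -r:r) {
      k <- k + 1L
      stack[[k]] <- shift_clamp2d(a, dx, dy)
      stack[[k + window^2]] <- shift_clamp2d(b, dx, dy)
    }
    arr <- array(unlist(stack), c(dim(a), 2L * window^2))
    med <- apply(arr, c(1, 2), stats::median)
    if (gaussian_sigma > 0) med <- gauss_smooth(med, gaussian_sigma)
    med
  }
  if (length(dim(scan1)) == 2L || is.null(dim(scan1))) {
    one_plane(as.matrix(scan1), as.matrix(scan2))
  } else {
    out <- array(0, dim(scan1))
    for (iz in seq_len(dim(scan1)[3]))
      out[, , iz] <- one_plane(scan1[, , iz], scan2[, , iz])
    out
  }
}
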