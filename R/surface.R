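#' Build a piecewise-linear 3D surface map from picked points
#'
#' Triangulates the XY projection of the input points (Delaunay) and
#' interpolates z linearly over each triangle, yielding a single-valued
#' height function `z(x, y)` defined inside the convex hull of the XY
#' coordinates and undefined (`NA`) outside it. The interpolant reproduces
#' the input points exactly. A regular evaluation grid is cached for fast
#' repeated queries during feature extraction.
#'
#' @param points data.frame or matrix with columns `x`, `y`, `z` (um);
#'   at least 3 non-collinear XY positions.
#' @param cache_spacing spacing of the cached evaluation grid (um).
#' @return object of class `lami_surface`.
#' @export
build_surface <- function(points, cache_spacing = 4) {
  pts <- as.data.frame(points)
  if (!all(c("x", "y", "z") %in% names(pts)))
    stop("`points` needs columns x, y, z")
  pts <- pts[!duplicated(pts[, c("x", "y")]), , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 distinct surface points")
  xy <- scale(as.matrix(pts[, c("x", "y")]), scale = FALSE)
  if (qr(xy)$rank < 2)
    stop("surface points are collinear in XY; cannot triangulate")
  xr <- range(pts$x); yr <- range(pts$y)
  gx <- seq(xr[1], xr[2], by = cache_spacing)
  gy <- seq(yr[1], yr[2], by = cache_spacing)
  if (length(gx) < 2) gx <- xr
  if (length(gy) < 2) gy <- yr
  cache <- interp::interp(pts$x, pts$y, pts$z, xo = gx, yo = gy,
                          method = "linear", output = "grid")
  gz <- cache$z
  # degenerate (co-circular) triangulations can leave thin NA seams inside
  # the hull; fill those cells from their neighbours, keeping the
  # outside-hull region undefined
  hull <- grDevices::chull(pts$x, pts$y)
  hx <- pts$x[hull]; hy <- pts$y[hull]
  in_hull <- function(x, y) {
    inside <- rep(TRUE, length(x))
    sgn <- 0
    nh <- length(hx)
    for (e in seq_len(nh)) {
      e2 <- if (e == nh) 1L else e + 1L
      s <- (hx[e2] - hx[e]) * (y - hy[e]) - (hy[e2] - hy[e]) * (x - hx[e])
      if (sgn == 0 && any(abs(s) > 1e-9)) sgn <- sign(s[which.max(abs(s))])
      inside <- inside & (s * sgn >= -1e-9)
    }
    inside
  }
  holes <- which(is.na(gz), arr.ind = TRUE)
  if (nrow(holes) > 0) {
    hin <- in_hull(gx[holes[, 1]], gy[holes[, 2]])
    holes <- holes[hin, , drop = FALSE]
    for (pass in seq_len(20)) {
      if (nrow(holes) == 0) break
      still <- rep(FALSE, nrow(holes))
      for (r in seq_len(nrow(holes))) {
        i <- holes[r, 1]; j <- holes[r, 2]
        nb <- c(if (i > 1) gz[i - 1, j], if (i < length(gx)) gz[i + 1, j],
                if (j > 1) gz[i, j - 1], if (j < length(gy)) gz[i, j + 1])
        nb <- nb[!is.na(nb)]
        if (length(nb) >= 2) gz[i, j] <- mean(nb) else still[r] <- TRUE
      }
      holes <- holes[still, , drop = FALSE]
    }
  }
  structure(list(points = pts, grid_x = gx, grid_y = gy,
                 grid_z = gz, cache_spacing = cache_spacing),
            class = "lami_surface")
}

#' @export
print.lami_surface <- function(x, ...) {
  cat("<lami_surface>", nrow(x$points), "points; hull bbox x",
      paste(signif(range(x$points$x), 4), collapse = ".."), "y",
      paste(signif(range(x$points$y), 4), collapse = ".."), "um\n")
  invisible(x)
}

#' Evaluate a surface map
#'
#' Returns the interpolated surface height at XY positions; `NA` outside
#' the convex hull of the input points ("undefined"). `exact = TRUE`
#' evaluates the piecewise-linear interpolant directly (exact at the input
#' points); the default uses the cached grid with bilinear lookup, which is
#' what the ray-distance search uses for speed.
#'
#' @param map a `lami_surface`.
#' @param x,y query positions (um), recycled to a common length.
#' @param exact evaluate the triangulation directly instead of the cache.
#' @return numeric vector of heights (um) with `NA` where undefined.
#' @export
surface_z <- function(map, x, y, exact = FALSE) {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  if (exact) {
    p <- map$points
    return(interp::interpp(p$x, p$y, p$z, xo = x, yo = y, linear = TRUE)$z)
  }
  gx <- map$grid_x; gy <- map$grid_y
  out <- rep(NA_real_, n)
  ok <- x >= gx[1] & x <= gx[length(gx)] & y >= gy[1] & y <= gy[length(gy)]
  if (!any(ok)) return(out)
  xi <- pmin(findInterval(x[ok], gx, rightmost.closed = TRUE), length(gx) - 1L)
  yi <- pmin(findInterval(y[ok], gy, rightmost.closed = TRUE), length(gy) - 1L)
  fx <- (x[ok] - gx[xi]) / (gx[xi + 1L] - gx[xi])
  fy <- (y[ok] - gy[yi]) / (gy[yi + 1L] - gy[yi])
  z <- map$grid_z
  v <- z[cbind(xi, yi)] * (1 - fx) * (1 - fy) +
    z[cbind(xi + 1L, yi)] * fx * (1 - fy) +
    z[cbind(xi, yi + 1L)] * (1 - fx) * fy +
    z[cbind(xi + 1L, yi + 1L)] * fx * fy
  out[ok] <- v
  out
}

#' Shape-feature configuration
#'
#' Parameters of the ray-distance descriptor: `n_rays` directions at a
#' common inclination `phi` to the optical axis with equally spaced
#' azimuths, distances binned into a histogram whose edges are `n_edges`
#' equally spaced points on [0, 1] passed through
#' `f(x) = x^exponent * d_max`, so short propagation distances (where
#' exponential scattering dynamics make differences most significant) get
#' finer bins. The in-tissue distance search is a binary search starting at
#' `search_start` and halving to `search_tol`.
#'
#' @param phi inclination to the optical axis (degrees, 0 < phi < 90).
#' @param n_rays number of azimuthal rays.
#' @param n_edges number of histogram edge points (bins = `n_edges - 1`).
#' @param exponent bin-edge power-law exponent.
#' @param d_max propagation distance beyond which no excitation is expected
#'   (um); the largest bin edge.
#' @param search_start initial binary-search distance (um).
#' @param search_tol binary-search tolerance (um).
#' @return list of class `lami_shape_config`.
#' @export
shape_config <- function(phi = 20, n_rays = 12, n_edges = n_rays + 1,
                         exponent = 1.5, d_max = 350,
                         search_start = 2000, search_tol = 1) {
  if (phi <= 0 || phi >= 90) stop("phi must lie strictly between 0 and 90 degrees")
  if (d_max <= 0) stop("d_max must be > 0")
  if (n_edges < 2) stop("need at least 2 histogram edges")
  structure(list(phi = phi, n_rays = n_rays, n_edges = n_edges,
                 exponent = exponent, d_max = d_max,
                 search_start = search_start, search_tol = search_tol),
            class = "lami_shape_config")
}

#' Histogram bin edges of the shape descriptor
#'
#' `n_edges` equally spaced points on [0, 1] through
#' `f(x) = x^exponent * d_max`; at defaults the largest edge is 350 um.
#'
#' @param config a `lami_shape_config`.
#' @return numeric vector of length `n_edges` (um).
#' @export
shape_bin_edges <- function(config = shape_config()) {
  seq(0, 1, length.out = config$n_edges)^config$exponent * config$d_max
}

#' In-tissue distance from focal points to the surface along rays
#'
#' Binary search for the smallest travel `t` at which `point + t * dir` is
#' above the surface interpolation or outside its domain (undefined counts
#' as above, exactly as the convex-hull test demands). The search starts at
#' `search_start` and halves the bracket until it is narrower than
#' `search_tol`.
#'
#' @param map a `lami_surface`.
#' @param points n x 3 matrix (or length-3 vector) of focal points (um).
#' @param directions n x 3 matrix of unit ray directions with an upward
#'   component (negative z, since z grows with depth).
#' @param config a `lami_shape_config` (supplies start and tolerance).
#' @return numeric vector of distances (um). Points already above the
#'   surface return 0 with a warning; rays that never cross within
#'   `search_start` return `search_start` and are marked in the
#'   `no_crossing` attribute.
#' @export
distance_to_surface <- function(map, points, directions,
                                config = shape_config()) {
  p <- as_point_matrix(points)
  u <- as_point_matrix(directions)
  if (nrow(u) == 1L && nrow(p) > 1L) u <- u[rep(1L, nrow(p)), , drop = FALSE]
  if (any(u[, 3] >= 0)) stop("ray directions must have an upward component")
  above <- function(t) {
    xs <- p[, 1] + t * u[, 1]
    ys <- p[, 2] + t * u[, 2]
    zs <- p[, 3] + t * u[, 3]
    s <- surface_z(map, xs, ys)
    is.na(s) | zs < s
  }
  n <- nrow(p)
  start_above <- above(rep(0, n))
  if (any(start_above))
    warning("some focal points are already above the surface; distance 0")
  hi <- rep(config$search_start, n)
  lo <- rep(0, n)
  no_cross <- !above(hi) & !start_above
  steps <- ceiling(log2(config$search_start / config$search_tol))
  active <- !start_above & !no_cross
  for (s in seq_len(steps)) {
    mid <- (lo + hi) / 2
    ab <- above(mid)
    hi[active & ab] <- mid[active & ab]
    lo[active & !ab] <- mid[active & !ab]
  }
  out <- hi
  out[start_above] <- 0
  out[no_cross] <- config$search_start
  attr(out, "no_crossing") <- no_cross
  out
}

# ray directions for the shape descriptor: inclination phi, azimuths
# 2*pi*k/n_rays with ray 0 along +x
shape_ray_directions <- function(config, phase = 0) {
  phi <- config$phi * pi / 180
  psi <- 2 * pi * (seq_len(config$n_rays) - 1) / config$n_rays + phase
  cbind(sin(phi) * cos(psi), sin(phi) * sin(psi), -cos(phi))
}

#' Ray-distance shape histogram at focal points
#'
#' Casts `n_rays` rays per focal point at inclination `phi` with equally
#' spaced azimuths, measures the in-tissue distance of each, and bins the
#' distances into the nonlinear edges of [shape_bin_edges()]. Distances
#' beyond the last edge are clamped into the last bin, so counts always sum
#' to `n_rays`.
#'
#' @inheritParams distance_to_surface
#' @param phase azimuthal phase of ray 0 (radians); irrelevant for
#'   rotationally symmetric surfaces.
#' @return integer matrix, one row per focal point, `n_edges - 1` columns.
#' @export
shape_histogram <- function(map, points, config = shape_config(), phase = 0) {
  p <- as_point_matrix(points)
  n <- nrow(p)
  u <- shape_ray_directions(config, phase)
  P <- p[rep(seq_len(n), each = config$n_rays), , drop = FALSE]
  U <- u[rep(seq_len(config$n_rays), times = n), , drop = FALSE]
  d <- distance_to_surface(map, P, U, config)
  edges <- shape_bin_edges(config)
  d <- pmin(pmax(d, 0), edges[length(edges)])
  bin <- pmin(pmax(findInterval(d, edges, rightmost.closed = TRUE), 1L),
              length(edges) - 1L)
  counts <- matrix(0L, n, length(edges) - 1L)
  pt <- rep(seq_len(n), each = config$n_rays)
  for (k in seq_len(config$n_rays)) {
    sel <- seq(k, length(bin), by = config$n_rays)
    counts[cbind(pt[sel], bin[sel])] <- counts[cbind(pt[sel], bin[sel])] + 1L
  }
  counts
}

#' Standard-candle feature vectors
#'
#' Concatenates, in fixed order: mean brightness, field XY position, and
#' the ray-distance histogram counts (15 elements at defaults). The
#' histogram encodes the microscope's rotational symmetry about its optical
#' axis by construction.
#'
#' @inheritParams shape_histogram
#' @param brightness measured mean brightness per focal point.
#' @param field_xy n x 2 matrix of XY positions within the field of view (um).
#' @return numeric matrix, one row per focal point, with named columns
#'   `brightness`, `field_x`, `field_y`, `hist_1` ... `hist_k`.
#' @export
featurize_points <- function(map, points, brightness, field_xy,
                             config = shape_config()) {
  p <- as_point_matrix(points)
  field_xy <- matrix(field_xy, ncol = 2)
  h <- shape_histogram(map, p, config)
  out <- cbind(brightness, field_xy, h)
  colnames(out) <- c("brightness", "field_x", "field_y",
                     paste0("hist_", seq_len(ncol(h))))
  out
}

#' @rdname featurize_points
#' @param point a single focal point (length-3, um).
#' @export
featurize <- function(map, point, brightness, field_xy,
                      config = shape_config()) {
  drop(featurize_points(map, matrix(point, ncol = 3), brightness,
                        matrix(field_xy, ncol = 2), config))
}
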