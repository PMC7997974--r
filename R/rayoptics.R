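#' Objective pupil model for ray-optics attenuation
#'
#' Describes the cone of excitation rays converging on the focal point: a
#' beam with a Gaussian amplitude profile (zero phase) at the back focal
#' plane of an objective of numerical aperture `na` in an immersion medium
#' of refractive index `index`. Rays are discretized on a polar x azimuthal
#' quadrature grid; each ray's weight combines the Gaussian intensity at
#' its back-focal-plane radius (Abbe sine mapping, radius proportional to
#' sin(theta)) with the annular area element, normalized to sum to 1.
#'
#' @param na numerical aperture (0 < na < index).
#' @param index immersion refractive index (water, 1.33).
#' @param fill fill factor: Gaussian amplitude 1/e radius at the back focal
#'   plane relative to the pupil radius.
#' @param n_theta,n_phi quadrature resolution (polar x azimuthal).
#' @return object of class `lami_pupil` with ray directions and weights.
#' @export
pupil_model <- function(na = 1.05, index = 1.33, fill = 1,
                        n_theta = 24, n_phi = 24) {
  if (na <= 0 || na >= index) stop("need 0 < na < index")
  theta_max <- asin(na / index)
  # midpoint rule in theta and phi
  th <- (seq_len(n_theta) - 0.5) / n_theta * theta_max
  ph <- (seq_len(n_phi) - 0.5) / n_phi * 2 * pi
  g <- expand.grid(theta = th, phi = ph)
  # Gaussian *amplitude* width fill * sin(theta_max) -> intensity exp(-2 r^2/w^2)
  w_int <- exp(-2 * (sin(g$theta) / (fill * sin(theta_max)))^2)
  w <- w_int * sin(g$theta) * cos(g$theta)
  structure(list(na = na, index = index, fill = fill,
                 theta = g$theta, phi = g$phi, weights = w / sum(w)),
            class = "lami_pupil")
}

#' Degenerate pupil containing only the axial ray
#'
#' Paraxial limit used for closed-form checks: all excitation travels along
#' the optical axis, so attenuation is exactly exponential in vertical
#' in-tissue path length.
#' @return a `lami_pupil` with a single vertical ray.
#' @export
paraxial_pupil <- function() {
  structure(list(na = 0, index = 1.33, fill = 1,
                 theta = 0, phi = 0, weights = 1),
            class = "lami_pupil")
}

# upward unit directions (toward the objective) for the pupil's rays
pupil_directions <- function(pupil) {
  cbind(sin(pupil$theta) * cos(pupil$phi),
        sin(pupil$theta) * sin(pupil$phi),
        -cos(pupil$theta))
}

#' Pupil-averaged excitation attenuation at focal points
#'
#' For each focal point inside the sample, computes
#' `A = sum_i w_i exp(-d_i / ls)` where `d_i` is the in-tissue path length
#' of pupil ray `i` from its surface entry to the focal point and `ls` the
#' sample's scattering mean free path. `A = 1` at the surface or for a
#' non-scattering sample (`ls = Inf`). Rays are treated independently
#' (scattered light is assumed lost), so a single per-ray exponential
#' captures both excitation scattering and any emission-path loss lumped
#' into `ls`.
#'
#' @param sample a `lami_sample`.
#' @param points n x 3 matrix (or length-3 vector) of focal points (um),
#'   all strictly inside the sample.
#' @param pupil a `lami_pupil` (default [pupil_model()] defaults).
#' @param ls override of the sample's mean free path (um).
#' @param chunk number of points per vectorized block.
#' @return numeric vector of attenuation factors in (0, 1].
#' @export
attenuation_factor <- function(sample, points, pupil = pupil_model(),
                               ls = sample$ls, chunk = 2000L) {
  p <- as_point_matrix(points)
  if (!all(sample_inside(sample, p)))
    stop("all focal points must lie inside the sample")
  u <- pupil_directions(pupil)
  w <- pupil$weights
  nr <- nrow(u)
  out <- numeric(nrow(p))
  for (i0 in seq(1L, nrow(p), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(p))
    idx <- i0:i1
    m <- length(idx)
    P <- p[rep(idx, each = nr), , drop = FALSE]
    U <- u[rep(seq_len(nr), times = m), , drop = FALSE]
    d <- ray_path_length(sample, P, U)
    e <- exp(-d / ls)
    out[idx] <- colSums(matrix(w * e, nrow = nr))
  }
  out
}

#' Monte-Carlo cross-check of the attenuation integral
#'
#' Estimates the same pupil-averaged attenuation as [attenuation_factor()]
#' with random ray directions (uniform in polar angle and azimuth, weighted
#' by the pupil density), providing an oracle independent of the
#' deterministic quadrature grid.
#'
#' @inheritParams attenuation_factor
#' @param point a single focal point (length-3, um).
#' @param n_rays number of random rays.
#' @param seed RNG seed.
#' @return scalar attenuation estimate.
#' @export
attenuation_factor_mc <- function(sample, point, pupil = pupil_model(),
                                  n_rays = 1e5, ls = sample$ls, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (pupil$na == 0) stop("Monte-Carlo check needs a non-degenerate pupil")
  theta_max <- asin(pupil$na / pupil$index)
  th <- stats::runif(n_rays, 0, theta_max)
  ph <- stats::runif(n_rays, 0, 2 * pi)
  w <- exp(-2 * (sin(th) / (pupil$fill * sin(theta_max)))^2) * sin(th) * cos(th)
  u <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), -cos(th))
  p <- matrix(rep(as.numeric(point), each = n_rays), ncol = 3)
  d <- ray_path_length(sample, p, u)
  sum(w * exp(-d / ls)) / sum(w)
}

#' Relative excitation power required at a focal point
#'
#' The factor by which input power must be increased to yield the same
#' two-photon fluorescence as without scattering: the reciprocal of the
#' pupil-averaged attenuation. Equals 1 at zero depth and grows
#' monotonically (sub-exponentially in a convex sample) with depth.
#'
#' @inheritParams attenuation_factor
#' @return numeric vector of factors >= 1.
#' @export
relative_power <- function(sample, points, pupil = pupil_model(),
                           ls = sample$ls) {
  1 / attenuation_factor(sample, points, pupil, ls = ls)
}

#' Precompute a relative-power lookup table for a spherical sample
#'
#' Relative excitation power for a sphere is parameterized by the vertical
#' distance from the focal point to the surface and the inclination of the
#' surface normal directly above it; this table evaluates the ray integral
#' on a (depth x angle) grid so later queries take microseconds instead of
#' the full quadrature.
#'
#' @param sample a spherical `lami_sample`.
#' @param pupil a `lami_pupil`.
#' @param depths strictly increasing vertical depths (um).
#' @param angles strictly increasing surface-normal angles (radians).
#' @return object of class `lami_lut` (grids plus a depth x angle matrix of
#'   relative-power values; `NA` where the geometry admits no such point).
#' @export
precompute_lut <- function(sample, pupil = pupil_model(),
                           depths = seq(0, 320, by = 8),
                           angles = seq(0, 70, by = 5) * pi / 180) {
  if (sample$geometry != "sphere") stop("LUT is defined for spherical samples")
  if (is.unsorted(depths, strictly = TRUE) || is.unsorted(angles, strictly = TRUE))
    stop("grids must be strictly increasing")
  R <- sample$radius
  vals <- matrix(NA_real_, length(depths), length(angles))
  for (j in seq_along(angles)) {
    g <- angles[j]
    s <- sample$center + R * c(sin(g), 0, -cos(g))
    # vertical chord below the surface point
    chord <- 2 * R * cos(g)
    ok <- depths > 0 & depths < chord - 1e-6
    pts <- cbind(s[1], s[2], s[3] + depths[ok])
    if (any(ok)) vals[ok, j] <- relative_power(sample, pts, pupil)
    vals[depths == 0, j] <- 1
  }
  structure(list(depths = depths, angles = angles, values = vals,
                 radius = R, ls = sample$ls),
            class = "lami_lut")
}

#' Bilinear lookup in a precomputed relative-power table
#'
#' Queries outside the table's grid are clamped to its edge with a warning.
#' Grid-node queries reproduce the precomputed values exactly.
#'
#' @param lut a `lami_lut` from [precompute_lut()].
#' @param depth vertical distances to the surface (um).
#' @param angle surface-normal angles (radians), recycled against `depth`.
#' @return numeric vector of relative-power factors (>= 1).
#' @export
lut_lookup <- function(lut, depth, angle) {
  n <- max(length(depth), length(angle))
  depth <- rep_len(depth, n); angle <- rep_len(angle, n)
  if (any(depth < min(lut$depths) - 1e-9 | depth > max(lut$depths) + 1e-9 |
          angle < min(lut$angles) - 1e-9 | angle > max(lut$angles) + 1e-9))
    warning("LUT query outside grid; clamped to table edge")
  depth <- clamp(depth, min(lut$depths), max(lut$depths))
  angle <- clamp(angle, min(lut$angles), max(lut$angles))
  di <- pmin(findInterval(depth, lut$depths,
                          rightmost.closed = TRUE), length(lut$depths) - 1L)
  ai <- pmin(findInterval(angle, lut$angles,
                          rightmost.closed = TRUE), length(lut$angles) - 1L)
  fd <- (depth - lut$depths[di]) / (lut$depths[di + 1L] - lut$depths[di])
  fa <- (angle - lut$angles[ai]) / (lut$angles[ai + 1L] - lut$angles[ai])
  v <- lut$values
  g <- function(i, j) v[cbind(i, j)]
  out <- g(di, ai) * (1 - fd) * (1 - fa) + g(di + 1L, ai) * fd * (1 - fa) +
    g(di, ai + 1L) * (1 - fd) * fa + g(di + 1L, ai + 1L) * fd * fa
  # fall back to nearest finite neighbour beyond the geometric validity edge
  nn <- is.na(out)
  if (any(nn)) {
    near <- g(di, ai)[nn]
    near[is.na(near)] <- max(v, na.rm = TRUE)
    out[nn] <- near
  }
  out
}

#' Spherical-model power policy for arbitrary samples
#'
#' Wraps a precomputed spherical lookup table into a power policy
#' `f(points) -> P0`: each focal point is reduced to (vertical depth below
#' the local top surface, local surface-normal angle) and the spherical
#' model's relative power is scaled by `amplitude`. This is the
#' physics-model baseline that assumes every sample is the calibration
#' sphere; applied to a non-spherical sample it carries the corresponding
#' model mismatch.
#'
#' @param lut a `lami_lut`.
#' @param sample the sample the policy will be applied to.
#' @param amplitude power at zero depth (relative units).
#' @return function mapping an n x 3 point matrix to base powers.
#' @export
make_lut_policy <- function(lut, sample, amplitude = 1) {
  force(lut); force(sample); force(amplitude)
  function(points) {
    p <- as_point_matrix(points)
    top <- sample_surface_height(sample, p[, 1], p[, 2])
    ang <- sample_normal_angle(sample, p[, 1], p[, 2])
    amplitude * lut_lookup(lut, pmax(p[, 3] - top, 0), ang)
  }
}

#' Imageable volume under different illumination strategies
#'
#' Shell/cap accounting of how much of a spherical sample each power-control
#' strategy can image with appropriate (neither under- nor over-) exposure:
#' \describe{
#'   \item{constant}{a thin spherical shell (`thickness`) at the top of the
#'     sample, reduced by `quarter` for the part shadowed at its rim.}
#'   \item{exponential_h, arbitrary_h_r}{a depth-reach `h` valid within a
#'     lateral radius `r`: cylinder `pi r^2 h` (stated approximation).}
#'   \item{surface_offset_r}{same cylinder form with the wider validity
#'     radius afforded by surface-relative offsetting.}
#'   \item{lami}{the full spherical shell from the surface down to the
#'     laser-power depth limit `max_depth`.}
#' }
#'
#' @param strategy one of `"constant"`, `"exponential_h"`,
#'   `"arbitrary_h_r"`, `"surface_offset_r"`, `"lami"`.
#' @param R sample radius (um).
#' @param thickness constant-illumination shell thickness (um).
#' @param quarter usable fraction of the constant-illumination shell.
#' @param h depth reach of depth-only modulation (um).
#' @param r lateral validity radius of a fixed depth profile (um).
#' @param max_depth maximum depth reachable at full laser power (um).
#' @return volume in um^3.
#' @export
imageable_volume <- function(strategy = c("constant", "exponential_h",
                                          "arbitrary_h_r", "surface_offset_r",
                                          "lami"),
                             R = 510, thickness = 25, quarter = 1 / 4,
                             h = NULL, r = NULL, max_depth = 300) {
  strategy <- match.arg(strategy)
  # per-strategy reach/validity defaults: an exponential profile holds to
  # ~140 um; arbitrary profiles reach the 300 um power limit; offsetting
  # relative to the surface widens the lateral validity radius
  if (is.null(h)) h <- if (strategy == "exponential_h") 140 else 300
  if (is.null(r)) r <- if (strategy == "surface_offset_r") 250 else 125
  if (thickness >= R) stop("shell thickness must be smaller than the radius")
  shell <- function(outer, inner) 4 / 3 * pi * (outer^3 - inner^3)
  switch(strategy,
    constant = shell(R, R - thickness) * quarter,
    exponential_h = pi * r^2 * h,
    arbitrary_h_r = pi * r^2 * min(h, max_depth),
    surface_offset_r = pi * r^2 * min(h, max_depth),
    lami = shell(R, R - max_depth))
}

#' Relative-power profile along a vertical line
#'
#' Tabulates the required relative power at increasing depth below a fixed
#' XY position and reports the second difference of its logarithm: zero for
#' an exactly exponential profile (flat sample, paraxial pupil), negative
#' (concave log-power, sub-exponential) for a convex sample.
#'
#' @param sample a `lami_sample`.
#' @param depths increasing vertical depths below the surface (um).
#' @param x,y XY position of the line (um).
#' @param pupil a `lami_pupil`.
#' @return data.frame with `depth`, `power` and `log_curvature` (second
#'   difference of log power; `NA` at the ends).
#' @export
required_power_profile <- function(sample, depths, x = NULL, y = NULL,
                                   pupil = pupil_model()) {
  if (is.null(x)) x <- switch(sample$geometry, flat = 0, sample$center[1])
  if (is.null(y)) y <- switch(sample$geometry, flat = 0, sample$center[2])
  top <- sample_surface_height(sample, x, y)
  pts <- cbind(x, y, top + depths)
  pw <- numeric(length(depths))
  pos <- depths > 0
  pw[pos] <- relative_power(sample, pts[pos, , drop = FALSE], pupil)
  pw[!pos] <- 1
  lc <- rep(NA_real_, length(depths))
  if (length(depths) >= 3) {
    lp <- log(pw)
    lc[2:(length(lp) - 1)] <- diff(lp, differences = 2)
  }
  data.frame(depth = depths, power = pw, log_curvature = lc)
}
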