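#' Construct a synthetic scattering sample
#'
#' Builds a phantom with homogeneous scattering (mean free path `ls`) and a
#' closed convex upper surface, used as ground truth for surface mapping,
#' attenuation and standard-candle simulation. Geometries: an infinite flat
#' slab, a sphere, an axis-aligned ellipsoid, or a union of two spherical
#' lobes (convex per lobe). The coordinate frame is right-handed with z
#' increasing with depth into the tissue (micrometers throughout).
#'
#' A radially symmetric vignette models the relative detection/excitation
#' sensitivity across the XY field of view: `cos^4`-like falloff equal to 1
#' at the field center and `1 - vignette_strength` at the field corner.
#'
#' @param geometry one of `"flat"`, `"sphere"`, `"ellipsoid"`, `"two_lobe"`.
#' @param ls scattering mean free path (um), > 0.
#' @param center 3D center for sphere/ellipsoid geometries (um).
#' @param radius sphere radius (um).
#' @param semiaxes ellipsoid semi-axes `(a, b, c)` (um).
#' @param lobes for `"two_lobe"`: list of two `list(center=, radius=)`.
#' @param z_top top surface height of the flat slab (um).
#' @param slab_depth thickness of the flat slab (um, may be `Inf`).
#' @param extent for the flat slab, half-width of the lateral footprint (um).
#' @param vignette_strength sensitivity drop at the field corner, in [0, 1).
#' @param fov XY field-of-view size used to normalize the vignette (um).
#' @return an object of class `lami_sample`.
#' @export
make_sample <- function(geometry = c("flat", "sphere", "ellipsoid", "two_lobe"),
                        ls = 100,
                        center = c(0, 0, 510),
                        radius = 510,
                        semiaxes = c(450, 350, 300),
                        lobes = NULL,
                        z_top = 0,
                        slab_depth = Inf,
                        extent = 1000,
                        vignette_strength = 0.15,
                        fov = 220) {
  geometry <- match.arg(geometry)
  if (!is.numeric(ls) || length(ls) != 1L || ls <= 0)
    stop("`ls` (scattering mean free path) must be a positive scalar")
  if (vignette_strength < 0 || vignette_strength >= 1)
    stop("`vignette_strength` must lie in [0, 1)")
  if (geometry == "sphere" && radius <= 0) stop("degenerate sphere: radius must be > 0")
  if (geometry == "ellipsoid" && any(semiaxes <= 0))
    stop("degenerate ellipsoid: all semi-axes must be > 0")
  if (geometry == "two_lobe") {
    if (is.null(lobes) || length(lobes) != 2L)
      stop("two_lobe geometry needs `lobes` = list of two list(center=, radius=)")
    for (lb in lobes)
      if (lb$radius <= 0) stop("degenerate lobe: radius must be > 0")
  }
  if (geometry == "flat" && slab_depth <= 0) stop("slab_depth must be > 0")
  structure(
    list(geometry = geometry, ls = ls, center = center, radius = radius,
         semiaxes = semiaxes, lobes = lobes, z_top = z_top,
         slab_depth = slab_depth, extent = extent,
         vignette_strength = vignette_strength, fov = fov),
    class = "lami_sample")
}

#' @export
print.lami_sample <- function(x, ...) {
  cat("<lami_sample>", x$geometry, " ls =", x$ls, "um\n")
  invisible(x)
}

as_point_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  if (ncol(p) != 3L) stop("points must be an n x 3 matrix (x, y, z in um)")
  p
}

#' Inside/outside query for a phantom sample
#'
#' @param sample a `lami_sample`.
#' @param points n x 3 matrix (or length-3 vector) of positions (um).
#' @return logical vector.
#' @export
sample_inside <- function(sample, points) {
  p <- as_point_matrix(points)
  switch(sample$geometry,
    flat = p[, 3] > sample$z_top & p[, 3] < sample$z_top + sample$slab_depth &
      abs(p[, 1]) < sample$extent & abs(p[, 2]) < sample$extent,
    sphere = {
      d <- sweep(p, 2, sample$center)
      rowSums(d^2) < sample$radius^2
    },
    ellipsoid = {
      d <- sweep(sweep(p, 2, sample$center), 2, sample$semiaxes, "/")
      rowSums(d^2) < 1
    },
    two_lobe = {
      ins <- rep(FALSE, nrow(p))
      for (lb in sample$lobes) {
        d <- sweep(p, 2, lb$center)
        ins <- ins | rowSums(d^2) < lb$radius^2
      }
      ins
    })
}

#' Height of the sample's top surface
#'
#' Returns the smallest z (shallowest point, since z grows with depth) of
#' the sample surface above each XY position, or `NA` where the sample has
#' no footprint.
#'
#' @param sample a `lami_sample`.
#' @param x,y XY coordinates (um), recycled to a common length.
#' @return numeric vector of surface heights (um), `NA` outside footprint.
#' @export
sample_surface_height <- function(sample, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  switch(sample$geometry,
    flat = rep_len(sample$z_top, n),
    sphere = {
      rho2 <- (x - sample$center[1])^2 + (y - sample$center[2])^2
      z <- sample$center[3] - sqrt(pmax(sample$radius^2 - rho2, 0))
      z[rho2 >= sample$radius^2] <- NA_real_
      z
    },
    ellipsoid = {
      a <- sample$semiaxes
      u2 <- ((x - sample$center[1]) / a[1])^2 + ((y - sample$center[2]) / a[2])^2
      z <- sample$center[3] - a[3] * sqrt(pmax(1 - u2, 0))
      z[u2 >= 1] <- NA_real_
      z
    },
    two_lobe = {
      z <- rep(NA_real_, n)
      for (lb in sample$lobes) {
        rho2 <- (x - lb$center[1])^2 + (y - lb$center[2])^2
        zi <- lb$center[3] - sqrt(pmax(lb$radius^2 - rho2, 0))
        zi[rho2 >= lb$radius^2] <- NA_real_
        z <- pmin(z, zi, na.rm = TRUE)
        z[is.infinite(z)] <- NA_real_
      }
      z
    })
}

#' Inclination of the surface normal above an XY position
#'
#' Angle (radians) between the outward surface normal at the top surface
#' point above `(x, y)` and the optical axis. 0 for a flat surface.
#'
#' @inheritParams sample_surface_height
#' @return numeric vector of angles (radians), `NA` outside footprint.
#' @export
sample_normal_angle <- function(sample, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  zs <- sample_surface_height(sample, x, y)
  switch(sample$geometry,
    flat = ifelse(is.na(zs), NA_real_, 0),
    sphere = {
      rho <- sqrt((x - sample$center[1])^2 + (y - sample$center[2])^2)
      ifelse(is.na(zs), NA_real_, asin(pmin(rho / sample$radius, 1)))
    },
    ellipsoid = {
      a <- sample$semiaxes
      # outward normal ~ gradient of the implicit form
      nx <- (x - sample$center[1]) / a[1]^2
      ny <- (y - sample$center[2]) / a[2]^2
      nz <- (zs - sample$center[3]) / a[3]^2
      ang <- acos(pmin(abs(nz) / sqrt(nx^2 + ny^2 + nz^2), 1))
      ifelse(is.na(zs), NA_real_, ang)
    },
    two_lobe = {
      # normal of whichever lobe provides the top surface
      best <- rep(NA_real_, n)
      for (lb in sample$lobes) {
        rho2 <- (x - lb$center[1])^2 + (y - lb$center[2])^2
        zi <- lb$center[3] - sqrt(pmax(lb$radius^2 - rho2, 0))
        zi[rho2 >= lb$radius^2] <- NA_real_
        take <- !is.na(zi) & (is.na(zs) | abs(zi - zs) < 1e-9)
        best[take] <- asin(pmin(sqrt(rho2[take]) / lb$radius, 1))
      }
      best
    })
}

# In-tissue path length from points p along unit directions u (upward rays
# have u[,3] < 0). Measure of {t >= 0 : p + t u inside sample}.
ray_path_length <- function(sample, p, u) {
  p <- as_point_matrix(p); u <- as_point_matrix(u)
  lobe_interval <- function(center, radius) {
    d <- sweep(p, 2, center)
    b <- rowSums(d * u)
    c0 <- rowSums(d^2) - radius^2
    disc <- b^2 - c0
    hit <- disc > 0
    sq <- sqrt(pmax(disc, 0))
    t0 <- ifelse(hit, -b - sq, NA_real_)
    t1 <- ifelse(hit, -b + sq, NA_real_)
    cbind(pmax(t0, 0), pmax(t1, 0))
  }
  switch(sample$geometry,
    flat = {
      # distance along the ray until z crosses z_top (rays must go upward)
      dz <- u[, 3]
      top <- (p[, 3] - sample$z_top) / pmax(-dz, 1e-12)
      bot <- if (is.finite(sample$slab_depth))
        (sample$z_top + sample$slab_depth - p[, 3]) / pmax(dz, 1e-12)
      else Inf
      ifelse(dz < 0, pmax(top, 0), pmax(bot, 0))
    },
    sphere = {
      iv <- lobe_interval(sample$center, sample$radius)
      iv[, 2] - iv[, 1]
    },
    ellipsoid = {
      a <- sample$semiaxes
      ps <- sweep(sweep(p, 2, sample$center), 2, a, "/")
      us <- sweep(u, 2, a, "/")
      nu <- sqrt(rowSums(us^2))
      us <- us / nu
      b <- rowSums(ps * us)
      c0 <- rowSums(ps^2) - 1
      disc <- b^2 - c0
      sq <- sqrt(pmax(disc, 0))
      t1 <- pmax(-b + sq, 0); t0 <- pmax(-b - sq, 0)
      ifelse(disc > 0, (t1 - t0) / nu, 0)
    },
    two_lobe = {
      iv1 <- lobe_interval(sample$lobes[[1]]$center, sample$lobes[[1]]$radius)
      iv2 <- lobe_interval(sample$lobes[[2]]$center, sample$lobes[[2]]$radius)
      iv1[is.na(iv1)] <- 0; iv2[is.na(iv2)] <- 0
      l1 <- iv1[, 2] - iv1[, 1]
      l2 <- iv2[, 2] - iv2[, 1]
      lo <- pmax(iv1[, 1], iv2[, 1])
      hi <- pmin(iv1[, 2], iv2[, 2])
      overlap <- pmax(hi - lo, 0)
      l1 + l2 - overlap
    })
}

#' Vignette (relative field sensitivity) at field positions
#'
#' `cos^4`-like radial falloff over the XY field of view, 1 at the field
#' center, `1 - vignette_strength` at the corner.
#'
#' @param sample a `lami_sample`.
#' @param field_x,field_y positions within the field of view (um, origin at
#'   the tile corner, so the field center is at `fov/2`).
#' @return sensitivities in (0, 1].
#' @export
vignette_at <- function(sample, field_x, field_y) {
  s <- sample$vignette_strength
  if (s == 0) return(rep(1, max(length(field_x), length(field_y))))
  half <- sample$fov / 2
  r <- sqrt((field_x - half)^2 + (field_y - half)^2) / (sqrt(2) * half)
  a <- acos((1 - s)^(1 / 4))
  cos(pmin(r, 1) * a)^4
}

#' Sample points on the top surface of a phantom
#'
#' Grid-samples the analytic top surface, e.g. to feed [build_surface()].
#'
#' @param sample a `lami_sample`.
#' @param spacing XY grid spacing (um).
#' @param pad margin beyond the footprint to drop (um); points whose XY lie
#'   outside the footprint are removed automatically.
#' @return data.frame with columns `x`, `y`, `z` (um).
#' @export
sample_surface_points <- function(sample, spacing = 50, pad = 0) {
  bb <- switch(sample$geometry,
    flat = c(-sample$extent, sample$extent, -sample$extent, sample$extent),
    sphere = c(sample$center[1] - sample$radius, sample$center[1] + sample$radius,
               sample$center[2] - sample$radius, sample$center[2] + sample$radius),
    ellipsoid = c(sample$center[1] - sample$semiaxes[1],
                  sample$center[1] + sample$semiaxes[1],
                  sample$center[2] - sample$semiaxes[2],
                  sample$center[2] + sample$semiaxes[2]),
    two_lobe = {
      cs <- sapply(sample$lobes, function(l) c(l$center[1:2], l$radius))
      c(min(cs[1, ] - cs[3, ]), max(cs[1, ] + cs[3, ]),
        min(cs[2, ] - cs[3, ]), max(cs[2, ] + cs[3, ]))
    })
  xs <- seq(bb[1] + pad, bb[2] - pad, by = spacing)
  ys <- seq(bb[3] + pad, bb[4] - pad, by = spacing)
  g <- expand.grid(x = xs, y = ys)
  # hexagonal offset of alternate rows avoids degenerate (co-circular)
  # configurations in downstream triangulation
  row_id <- match(g$y, ys)
  g$x <- g$x + (row_id %% 2) * spacing / 2
  g$z <- sample_surface_height(sample, g$x, g$y)
  g[!is.na(g$z), , drop = FALSE]
}

#' Seed standard-candle cells inside a phantom
#'
#' Positions are uniform over the sample interior down to `max_depth` below
#' the local top surface. Intrinsic brightness factors `b` are lognormal
#' with population mean 1 and coefficient of variation `brightness_cv`,
#' independent of position.
#'
#' @param sample a `lami_sample`.
#' @param n number of candles (>= 1).
#' @param brightness_cv lognormal CV of the intrinsic brightness factor.
#' @param max_depth maximum vertical depth below the surface (um).
#' @param min_depth minimum vertical depth (um).
#' @param seed RNG seed (fixed seed gives bit-identical output).
#' @return data.frame with columns `id`, `x`, `y`, `z`, `b`.
#' @export
seed_candles <- function(sample, n, brightness_cv = 0.15, max_depth = 300,
                         min_depth = 2, seed = NULL) {
  if (n < 1) stop("`n` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sp <- sample_surface_points(sample, spacing = 25)
  bb <- c(range(sp$x), range(sp$y))
  zr <- range(sp$z)
  keep <- matrix(numeric(0), 0, 3)
  tries <- 0L
  while (nrow(keep) < n) {
    tries <- tries + 1L
    if (tries > 2000L)
      stop("rejection sampling stalled: sample interior too small for `n` candles")
    m <- max(4L * n, 1000L)
    cand <- cbind(stats::runif(m, bb[1], bb[2]),
                  stats::runif(m, bb[3], bb[4]),
                  stats::runif(m, zr[1] + min_depth, zr[2] + max_depth))
    ok <- sample_inside(sample, cand)
    top <- sample_surface_height(sample, cand[, 1], cand[, 2])
    depth <- cand[, 3] - top
    ok <- ok & !is.na(top) & depth >= min_depth & depth <= max_depth
    keep <- rbind(keep, cand[ok, , drop = FALSE])
  }
  keep <- keep[seq_len(n), , drop = FALSE]
  if (brightness_cv > 0) {
    sdlog <- sqrt(log(1 + brightness_cv^2))
    b <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else b <- rep(1, n)
  data.frame(id = seq_len(n), x = keep[, 1], y = keep[, 2], z = keep[, 3], b = b)
}
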