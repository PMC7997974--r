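# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
gaussian_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur along one margin of a 2D/3D array, zero-padded.
convolve_margin <- function(a, k, margin) {
  d <- dim(a)
  r <- (length(k) - 1L) / 2L
  out <- array(0, d)
  idx <- function(shift) {
    # returns source/dest index vectors along `margin` for a given shift
    n <- d[margin]
    src <- seq_len(n) + shift
    keep <- src >= 1L & src <= n
    list(src = src[keep], dst = seq_len(n)[keep])
  }
  for (j in seq_along(k)) {
    s <- j - r - 1L
    ii <- idx(s)
    if (length(ii$src) == 0L) next
    if (length(d) == 2L) {
      if (margin == 1L) out[ii$dst, ] <- out[ii$dst, ] + k[j] * a[ii$src, ]
      else out[, ii$dst] <- out[, ii$dst] + k[j] * a[, ii$src]
    } else {
      if (margin == 1L) out[ii$dst, , ] <- out[ii$dst, , ] + k[j] * a[ii$src, , ]
      else if (margin == 2L) out[, ii$dst, ] <- out[, ii$dst, ] + k[j] * a[, ii$src, ]
      else out[, , ii$dst] <- out[, , ii$dst] + k[j] * a[, , ii$src]
    }
  }
  out
}

#' Separable Gaussian smoothing of a 2D or 3D array
#'
#' Zero-padded separable convolution; `sigma` may be a scalar or one value
#' per array dimension (in pixels/voxels). A sigma of 0 skips that axis.
#' @param a numeric array (2D or 3D).
#' @param sigma Gaussian standard deviation(s) in pixels.
#' @return array of the same shape.
#' @export
gauss_smooth <- function(a, sigma) {
  d <- dim(a)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("`a` must be a 2D or 3D array")
  sigma <- rep(sigma, length.out = length(d))
  for (m in seq_along(d)) {
    if (sigma[m] > 0) a <- convolve_margin(a, gaussian_kernel1d(sigma[m]), m)
  }
  a
}

# n-dimensional circular cross-correlation via FFT (mean-removed).
# Returns an array C with C[s+1] (0-based shift s, wrapped) equal to
# sum_x a(x) * b(x - s): the argmax locates the shift by which `b` must be
# translated to best match `a`.
cross_correlate <- function(a, b, demean = TRUE) {
  if (!identical(dim(a), dim(b))) stop("arrays must share a shape")
  if (demean) {
    a <- a - mean(a)
    b <- b - mean(b)
  }
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / length(a)
}

# Convert a 0-based circular shift index to a signed shift in [-n/2, n/2).
wrap_shift <- function(i0, n) ifelse(i0 > n / 2, i0 - n, i0)

# Integer circular shift of an nd array: element x of the result takes the
# value of `a` at x - s (so the content moves by +s).
circ_shift <- function(a, s) {
  d <- dim(a)
  idx <- lapply(seq_along(d), function(m) {
    ((seq_len(d[m]) - 1L - s[m]) %% d[m]) + 1L
  })
  do.call(`[`, c(list(a), idx))
}

# Bilinear sub-pixel translation of a 2D image by (dx, dy) with zero
# padding: output(x, y) = input(x - dx, y - dy).
shift_bilinear <- function(im, dx, dy) {
  d <- dim(im)
  xs <- seq_len(d[1]) - dx
  ys <- seq_len(d[2]) - dy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  at <- function(ix, iy) {
    ok_x <- ix >= 1 & ix <= d[1]
    ok_y <- iy >= 1 & iy <= d[2]
    m <- matrix(0, d[1], d[2])
    if (any(ok_x) && any(ok_y))
      m[ok_x, ok_y] <- im[ix[ok_x], iy[ok_y], drop = FALSE]
    m
  }
  at(x0, y0) * outer(1 - fx, 1 - fy) +
    at(x0 + 1, y0) * outer(fx, 1 - fy) +
    at(x0, y0 + 1) * outer(1 - fx, fy) +
    at(x0 + 1, y0 + 1) * outer(fx, fy)
}

# Trilinear sub-voxel translation of a 3D volume (zero padding):
# output(v) = input(v - s).
shift_trilinear <- function(vol, s) {
  d <- dim(vol)
  g0 <- floor(s)
  f <- s - g0
  out <- array(0, d)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[1] else 1 - f[1]) *
      (if (cy) f[2] else 1 - f[2]) *
      (if (cz) f[3] else 1 - f[3])
    if (w == 0) next
    sh <- g0 + c(cx, cy, cz)
    src <- lapply(1:3, function(m) seq_len(d[m]) - sh[m])
    keep <- lapply(1:3, function(m) src[[m]] >= 1 & src[[m]] <= d[m])
    dst <- lapply(1:3, function(m) seq_len(d[m])[keep[[m]]])
    srk <- lapply(1:3, function(m) src[[m]][keep[[m]]])
    if (any(vapply(dst, length, 1L) == 0L)) next
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]], drop = FALSE] +
      w * vol[srk[[1]], srk[[2]], srk[[3]], drop = FALSE]
  }
  out
}

# 6-connected components of a 3D logical mask. Returns an integer label
# array (0 = background). Frontier-propagation implementation.
label_components3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nbr_offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                       c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  lin <- function(coord) {
    (coord[, 3] - 1L) * d[1] * d[2] + (coord[, 2] - 1L) * d[1] + coord[, 1]
  }
  todo <- which(mask)
  cur <- 0L
  while (length(todo) > 0L) {
    seed <- todo[1]
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier) > 0L) {
      cz <- (frontier - 1L) %/% (d[1] * d[2]) + 1L
      rem <- (frontier - 1L) %% (d[1] * d[2])
      cy <- rem %/% d[1] + 1L
      cx <- rem %% d[1] + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(nbr_offsets))) {
        nx <- cx + nbr_offsets[k, 1]
        ny <- cy + nbr_offsets[k, 2]
        nz <- cz + nbr_offsets[k, 3]
        ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] &
          nz >= 1L & nz <= d[3]
        if (!any(ok)) next
        cand <- lin(cbind(nx[ok], ny[ok], nz[ok]))
        cand <- cand[mask[cand] & lab[cand] == 0L]
        if (length(cand)) {
          lab[cand] <- cur
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
    todo <- todo[lab[todo] == 0L]
  }
  lab
}

# voxel linear index -> (x, y, z) matrix
index_to_coord3d <- function(i, d) {
  cz <- (i - 1L) %/% (d[1] * d[2]) + 1L
  rem <- (i - 1L) %% (d[1] * d[2])
  cbind(x = rem %% d[1] + 1L, y = rem %/% d[1] + 1L, z = cz)
}
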