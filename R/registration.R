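# Three-stage MAP registration/stitching and the online Z-drift estimator.
#
# Stage 1 removes breathing-induced per-plane XY shifts within a Z-stack by
# minimizing the normalized mean-squared difference between consecutive
# planes plus a quadratic shift penalty. Stage 2 removes whole-stack 3D
# motion between consecutive time points by cross-correlation. Stage 3
# finds stitching offsets between tiled Z-stacks by maximizing the mean
# correlation coefficient over pairwise overlaps with trust-region Newton.

# bilinear sub-pixel translation of a 2D image together with its exact
# partial derivatives with respect to the shift
shift_bilinear_grad <- function(im, dx, dy) {
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
  c00 <- at(x0, y0); c10 <- at(x0 + 1, y0)
  c01 <- at(x0, y0 + 1); c11 <- at(x0 + 1, y0 + 1)
  val <- c00 * outer(1 - fx, 1 - fy) + c10 * outer(fx, 1 - fy) +
    c01 * outer(1 - fx, fy) + c11 * outer(fx, fy)
  # d val / d dx = -d val / d fx, and fx = xs - x0 with xs = x - dx
  gx <- (c00 - c10) * outer(rep(1, d[1]), 1 - fy) +
    (c01 - c11) * outer(rep(1, d[1]), fy)
  gy <- (c00 - c01) * outer(1 - fx, rep(1, d[2])) +
    (c10 - c11) * outer(fx, rep(1, d[2]))
  list(val = val, gx = gx, gy = gy)
}

# one optimization pass of the per-plane shift model on a fixed image set
align_slices_pass <- function(planes, shifts, lambda, lr, patience,
                              max_iter, mask, norm, decays = 2L) {
  N <- length(planes)
  nc <- length(planes[[1]])
  objective <- function(S) {
    tot <- 0
    for (j in seq_len(N - 1)) for (c in seq_len(nc))
      tot <- tot + sum(((S[[j]][[c]] - S[[j + 1]][[c]]) * mask)^2)
    tot
  }
  resample_all <- function(sh) {
    lapply(seq_len(N), function(j)
      lapply(seq_len(nc), function(c)
        shift_bilinear_grad(planes[[j]][[c]], sh[j, 1], sh[j, 2])))
  }
  R <- resample_all(shifts)
  vals <- lapply(R, function(pj) lapply(pj, `[[`, "val"))
  cur <- objective(vals) / norm + lambda * sum(shifts^2)
  best <- list(s = shifts, loss = cur)
  loss_hist <- cur
  m <- matrix(0, N, 2); v <- matrix(0, N, 2)
  beta1 <- 0.9; beta2 <- 0.999
  bad <- 0L
  for (it in seq_len(max_iter)) {
    g <- matrix(0, N, 2)
    for (j in seq_len(N)) for (c in seq_len(nc)) {
      gx <- R[[j]][[c]]$gx; gy <- R[[j]][[c]]$gy
      if (j < N) {
        res <- (R[[j]][[c]]$val - R[[j + 1]][[c]]$val) * mask^2
        g[j, 1] <- g[j, 1] + 2 * sum(res * gx)
        g[j, 2] <- g[j, 2] + 2 * sum(res * gy)
      }
      if (j > 1) {
        res <- (R[[j - 1]][[c]]$val - R[[j]][[c]]$val) * mask^2
        g[j, 1] <- g[j, 1] - 2 * sum(res * gx)
        g[j, 2] <- g[j, 2] - 2 * sum(res * gy)
      }
    }
    g <- g / norm + 2 * lambda * shifts
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    shifts <- shifts - lr * (m / (1 - beta1^it)) /
      (sqrt(v / (1 - beta2^it)) + 1e-8)
    R <- resample_all(shifts)
    vals <- lapply(R, function(pj) lapply(pj, `[[`, "val"))
    cur <- objective(vals) / norm + lambda * sum(shifts^2)
    loss_hist <- c(loss_hist, cur)
    if (cur < best$loss - 1e-12) {
      best <- list(s = shifts, loss = cur)
      bad <- 0L
    } else bad <- bad + 1L
    if (bad >= patience) {
      # restore the best shifts and anneal the Adam step before giving
      # up: unit steps overshoot once the residual is sub-pixel
      if (decays > 0L) {
        decays <- decays - 1L
        lr <- lr / 3
        shifts <- best$s
        R <- resample_all(shifts)
        m[] <- 0; v[] <- 0   # stale momentum would push off the optimum
        bad <- 0L
      } else break
    }
  }
  list(shifts = best$s, loss = loss_hist)
}

#' Correct per-plane XY motion inside a Z-stack
#'
#' Estimates one corrective XY shift per plane by minimizing the sum of
#' pixel-wise mean-squared differences between consecutive planes,
#' normalized by the total squared intensity (so the learning rate is
#' independent of stack brightness), plus a quadratic penalty
#' `lambda * (||x||^2 + ||y||^2)` encoding the prior that shifts are small.
#' Optimization uses Adam; it stops once the objective has failed to
#' decrease for `patience` iterations. A border fraction of pixels is
#' excluded from the loss (bilinear resampling zero-pads there).
#'
#' @param volume 3D array (x, y, z) or 4D array (x, y, z, channel).
#' @param lambda regularization weight.
#' @param lr Adam learning rate (pixels).
#' @param patience iterations without improvement before stopping.
#' @param max_iter hard iteration cap.
#' @param exclude_channel channel index to drop (e.g. the SHG channel), or
#'   `NULL`.
#' @param border fraction of pixels masked at each image edge.
#' @param init `"xcorr"` initializes the shifts from the integer argmax of
#'   pairwise plane cross-correlations (cumulated and de-meaned), so the
#'   gradient refinement starts inside the attraction basin; `"zero"`
#'   starts from rest.
#' @param presmooth sigmas (pixels) of Gaussian coarse-to-fine stages run
#'   before the full-resolution pass; each widens the attraction basin.
#'   Off by default (the cross-correlation initializer covers large
#'   shifts).
#' @return list with `shifts` (planes x 2 matrix of corrective shifts, in
#'   pixels), `corrected` volume, and `loss` history (final pass).
#' @export
align_slices <- function(volume, lambda = 8e-3, lr = 1, patience = 10,
                         max_iter = 300, exclude_channel = NULL,
                         border = 0.05, init = c("xcorr", "zero"),
                         presmooth = numeric(0)) {
  init <- match.arg(init)
  d <- dim(volume)
  in_3d <- length(d) == 3L
  if (in_3d) volume <- array(volume, c(d, 1L))
  d <- dim(volume)
  chans <- setdiff(seq_len(d[4]), exclude_channel)
  if (d[3] < 2) stop("need at least 2 planes")
  norm <- sum(volume[, , , chans]^2)
  if (norm == 0) stop("all-zero image: loss normalizer is zero")
  bx <- ceiling(border * d[1]); by <- ceiling(border * d[2])
  mask <- matrix(0, d[1], d[2])
  mask[(bx + 1):(d[1] - bx), (by + 1):(d[2] - by)] <- 1
  planes <- lapply(seq_len(d[3]), function(j)
    lapply(chans, function(c) volume[, , j, c]))
  N <- d[3]
  shifts <- matrix(0, N, 2)
  if (init == "xcorr" && N > 1) {
    summed <- lapply(planes, function(pj) Reduce(`+`, pj))
    rel <- matrix(0, N - 1, 2)
    for (j in seq_len(N - 1)) {
      if (stats::sd(summed[[j]]) == 0 || stats::sd(summed[[j + 1]]) == 0) next
      cc <- cross_correlate(summed[[j + 1]], summed[[j]])
      i <- which.max(cc)
      dd <- dim(cc)
      co <- c((i - 1) %% dd[1] + 1, (i - 1) %/% dd[1] + 1)
      rel[j, ] <- vapply(1:2, function(m) wrap_shift(co[m] - 1, dd[m]), 0)
    }
    cum <- rbind(c(0, 0), apply(rel, 2, cumsum))
    shifts <- -sweep(cum, 2, colMeans(cum))
  }
  for (sg in presmooth[presmooth > 0]) {
    coarse <- lapply(planes, function(pj) lapply(pj, gauss_smooth, sg))
    norm_c <- sum(unlist(lapply(coarse, function(pj)
      lapply(pj, function(m) sum(m^2)))))
    # coarse stages only initialize the shifts: smoothing drains the data
    # term, so applying the full penalty here would collapse them to zero
    shifts <- align_slices_pass(coarse, shifts, lambda = 0, lr, patience,
                                max_iter, mask, norm_c)$shifts
  }
  fit <- align_slices_pass(planes, shifts, lambda, lr, patience, max_iter,
                           mask, norm)
  shifts <- fit$shifts
  corrected <- volume
  for (j in seq_len(N)) for (c in seq_len(d[4]))
    corrected[, , j, c] <- shift_bilinear(volume[, , j, c],
                                          shifts[j, 1], shifts[j, 2])
  if (in_3d) corrected <- array(corrected, d[1:3])
  list(shifts = shifts, corrected = corrected, loss = fit$loss)
}

#' Integer 3D shift between consecutive time points
#'
#' Argmax of the (mean-removed, FFT) 3D cross-correlation between two
#' same-shape stacks: the returned shift moves `previous` onto `current`.
#' Multi-channel input (4D) sums the correlation over channels.
#'
#' @param current,previous 3D arrays (or 4D with channels last).
#' @return integer vector `c(dx, dy, dz)` in voxels.
#' @export
align_time <- function(current, previous) {
  if (length(dim(current)) == 4L) {
    cc <- 0
    for (c in seq_len(dim(current)[4]))
      cc <- cc + cross_correlate(current[, , , c], previous[, , , c])
  } else {
    if (stats::sd(current) == 0 || stats::sd(previous) == 0)
      stop("flat (zero-variance) stack: cross-correlation undefined")
    cc <- cross_correlate(current, previous)
  }
  d <- dim(cc)
  i <- which.max(cc)
  co <- index_to_coord3d(i, d)
  vapply(1:3, function(m) as.integer(wrap_shift(co[1, m] - 1L, d[m])), 1L)
}

#' Cumulative drift of a stack series over time
#'
#' Pairwise [align_time()] shifts between consecutive time points, summed
#' cumulatively into an absolute shift per time point (first = 0).
#'
#' @param stacks list of same-shape 3D (or 4D) arrays ordered in time.
#' @return integer matrix (time points x 3).
#' @export
align_time_series <- function(stacks) {
  n <- length(stacks)
  out <- matrix(0L, n, 3)
  for (t in seq_len(n - 1))
    out[t + 1, ] <- out[t, ] + align_time(stacks[[t + 1]], stacks[[t]])
  colnames(out) <- c("dx", "dy", "dz")
  out
}

#' Autofluorescence pseudo-channel
#'
#' Minimum pixel value over several channels: broad-spectrum
#' autofluorescent structures survive while single-channel labels vanish,
#' giving an immobile fiducial signal for stitching.
#'
#' @param volume 4D array (x, y, z, channel).
#' @param channels channels to combine.
#' @return 3D array.
#' @export
min_channel_fiducial <- function(volume, channels = seq_len(dim(volume)[4])) {
  out <- volume[, , , channels[1]]
  for (c in channels[-1]) out <- pmin(out, volume[, , , c])
  out
}

# values of `vol` sampled at window coords (i-frame) minus rel, trilinear;
# idx is a list of 3 integer index vectors in the i frame
sample_rel <- function(vol, rel, idx) {
  base <- floor(rel); f <- rel - base
  d <- dim(vol)
  acc <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[1] else 1 - f[1]) *
      (if (cy) f[2] else 1 - f[2]) * (if (cz) f[3] else 1 - f[3])
    if (w == 0) next
    sx <- idx[[1]] - base[1] - cx
    sy <- idx[[2]] - base[2] - cy
    sz <- idx[[3]] - base[3] - cz
    kx <- clamp(sx, 1L, d[1]); ky <- clamp(sy, 1L, d[2]); kz <- clamp(sz, 1L, d[3])
    acc <- acc + w * vol[kx, ky, kz, drop = FALSE]
  }
  acc
}

# mean correlation coefficient over overlapping regions of all adjacent
# pairs, given absolute offsets (rows of `off`, voxels)
stitch_objective <- function(stacks, off, pairs, min_overlap = 3) {
  vals <- c()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    di <- dim(stacks[[i]]); dj <- dim(stacks[[j]])
    rel <- off[j, ] - off[i, ]
    lo <- pmax(1, ceiling(rel + 1))
    hi <- pmin(di, floor(rel + dj))
    if (any(hi - lo + 1 < min_overlap)) next
    idx <- lapply(1:3, function(m) seq(lo[m], hi[m]))
    a <- stacks[[i]][idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    b <- sample_rel(stacks[[j]], rel, idx)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance overlap for pair (", i, ",", j, "); skipped")
      next
    }
    vals <- c(vals, stats::cor(as.vector(a), as.vector(b)))
  }
  if (length(vals) == 0) stop("no usable overlapping pairs")
  mean(vals)
}

#' Stitch tiled Z-stacks by overlap correlation
#'
#' Each stack is parameterized by a 3-element XYZ offset (the first stack
#' is pinned at its nominal position). The loss is the mean of the
#' correlation coefficients of the voxels in the overlapping regions of
#' every adjacent pair — correlation, not plain cross-correlation, so
#' brightness rescaling between tiles does not move the optimum. Stacks
#' from a time series should be averaged before calling (the relative
#' time-point motion having been removed by [align_time_series()]).
#' Optimization is Newton's method with a trust-region constraint, with
#' finite-difference gradient and Hessian over the small parameter space.
#'
#' @param stacks list of 3D arrays (one channel, e.g. a fiducial channel or
#'   [min_channel_fiducial()] output).
#' @param nominal matrix (stacks x 3) of nominal voxel offsets from the
#'   tile layout.
#' @param pairs optional 2-column matrix of adjacent pairs; default: all
#'   pairs whose nominal bounding boxes overlap.
#' @param max_iter trust-region iterations.
#' @param delta0 initial trust radius (voxels).
#' @param max_voxels voxel budget per stack; larger stacks are decimated
#'   2x per axis until they fit (offsets are still reported in original
#'   voxels, at correspondingly coarser resolution).
#' @return list with `offsets` (stacks x 3, absolute voxels) and the final
#'   mean overlap `correlation`.
#' @export
stitch_stacks <- function(stacks, nominal, pairs = NULL, max_iter = 40,
                          delta0 = 2, max_voxels = 2e7) {
  n <- length(stacks)
  nominal <- matrix(nominal, n, 3)
  scale <- 1
  while (max(vapply(stacks, function(s) prod(dim(s)), 0)) > max_voxels) {
    stacks <- lapply(stacks, function(s) {
      d <- dim(s)
      s[seq(1, d[1], by = 2), seq(1, d[2], by = 2), seq(1, d[3], by = 2),
        drop = FALSE]
    })
    nominal <- nominal / 2
    scale <- scale * 2
  }
  if (is.null(pairs)) {
    pairs <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      rel <- nominal[j, ] - nominal[i, ]
      if (all(rel + 1 <= dim(stacks[[i]])) &&
          all(rel + dim(stacks[[j]]) >= 1))
        pairs <- rbind(pairs, c(i, j))
    }
  }
  if (is.null(pairs) || nrow(pairs) == 0) stop("no overlapping pairs declared")
  theta0 <- rep(0, 3 * (n - 1))
  obj <- function(theta) {
    off <- nominal
    if (n > 1) off[-1, ] <- nominal[-1, , drop = FALSE] +
        matrix(theta, n - 1, 3, byrow = TRUE)
    -stitch_objective(stacks, off, pairs)
  }
  theta <- theta0
  f0 <- obj(theta)
  delta <- delta0
  eps <- 0.25
  np <- length(theta)
  for (it in seq_len(max_iter)) {
    # finite-difference gradient and Hessian
    g <- numeric(np)
    H <- matrix(0, np, np)
    fp <- numeric(np); fm <- numeric(np)
    for (k in seq_len(np)) {
      tp <- theta; tp[k] <- tp[k] + eps
      tm <- theta; tm[k] <- tm[k] - eps
      fp[k] <- obj(tp); fm[k] <- obj(tm)
      g[k] <- (fp[k] - fm[k]) / (2 * eps)
      H[k, k] <- (fp[k] - 2 * f0 + fm[k]) / eps^2
    }
    if (np > 1) {
      for (k in seq_len(np - 1)) for (l in (k + 1):np) {
        tpp <- theta; tpp[k] <- tpp[k] + eps; tpp[l] <- tpp[l] + eps
        H[k, l] <- H[l, k] <-
          (obj(tpp) - fp[k] - fp[l] + f0) / eps^2
      }
    }
    # trust-region step: regularize the Hessian until the step is
    # acceptable and within the radius
    mu <- 0
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-6) mu <- 1e-6 - min(ev)
    step <- NULL
    repeat {
      step <- tryCatch(-solve(H + mu * diag(np), g), error = function(e) NULL)
      if (!is.null(step) && sqrt(sum(step^2)) <= delta) break
      mu <- max(mu * 4, 1e-4)
      if (mu > 1e6) { step <- -delta * g / max(sqrt(sum(g^2)), 1e-12); break }
    }
    f1 <- obj(theta + step)
    pred <- -(sum(g * step) + 0.5 * sum(step * (H %*% step)))
    rho <- if (pred > 0) (f0 - f1) / pred else -1
    if (f1 < f0) {
      theta <- theta + step
      f0 <- f1
      if (rho > 0.75) delta <- min(delta * 2, 8)
    } else {
      delta <- delta / 2
    }
    if (delta < 0.05 || sqrt(sum(g^2)) < 1e-6) break
  }
  off <- nominal
  if (n > 1) off[-1, ] <- nominal[-1, , drop = FALSE] +
      matrix(theta, n - 1, 3, byrow = TRUE)
  list(offsets = off * scale, correlation = -f0)
}

#' Drift-estimator state
#'
#' Exponential moving average of the Z-drift rate used to pre-compensate
#' the next acquisition step.
#'
#' @param rate initial drift rate (planes per time step).
#' @param weight EMA weight on the newest observation, in (0, 1].
#' @return list of class `lami_drift_state`.
#' @export
drift_state <- function(rate = 0, weight = 0.5) {
  structure(list(rate = rate, weight = weight, last_offset = 0),
            class = "lami_drift_state")
}

#' Sub-plane Z drift between consecutive time points
#'
#' Takes the 3D cross-correlation of the two volumes (e.g. the SHG
#' channel), reduces it to its maximum within every 2D slice, fits a cubic
#' spline to these per-lag maxima and returns the argmax of the smooth
#' curve: a Z offset with subpixel (sub-plane) accuracy. The offset updates
#' an exponential moving average of the drift rate so both the current
#' correction and the predicted next-step drift are available.
#'
#' @param current,previous 3D arrays (same shape, >= 4 planes).
#' @param state a `lami_drift_state` (or `NULL` to start fresh).
#' @return list with `offset` (planes, continuous), `predicted` next-step
#'   drift, and the updated `state`.
#' @export
estimate_z_drift <- function(current, previous, state = NULL) {
  if (is.null(state)) state <- drift_state()
  d <- dim(current)
  if (d[3] < 4) stop("need at least 4 planes for the spline fit")
  cc <- cross_correlate(current, previous)
  lags <- wrap_shift(seq_len(d[3]) - 1L, d[3])
  m <- apply(cc, 3, max)
  ord <- order(lags)
  lags <- lags[ord]; m <- m[ord]
  # restrict to at most +/- quarter-stack lags around the peak
  if (max(m) - min(m) < 1e-12) {
    warning("flat correlation maxima; drift offset set to 0")
    offset <- 0
  } else {
    sp <- stats::splinefun(lags, m, method = "natural")
    opt <- stats::optimize(sp, range(lags), maximum = TRUE)
    offset <- opt$maximum
  }
  w <- state$weight
  state$rate <- w * offset + (1 - w) * state$rate
  state$last_offset <- offset
  list(offset = offset, predicted = state$rate, state = state)
}
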