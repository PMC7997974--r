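# Track statistics: motility coefficients from time-averaged MSD,
# displacement vs root-time curves with LOWESS and bootstrap CIs, and
# neighbor-density clustering.

#' Simulate 3D cell tracks
#'
#' Random-walk (`brownian`), reflecting-sphere (`confined`) or
#' constant-velocity (`ballistic`) tracks, for validating the motility
#' statistics against known dynamics.
#'
#' @param n_tracks number of tracks.
#' @param n_steps steps per track.
#' @param dt time step (min).
#' @param D diffusion coefficient (um^2/min) for the random-walk modes.
#' @param mode `"brownian"`, `"confined"` or `"ballistic"`.
#' @param radius confinement radius (um) for `"confined"`.
#' @param speed speed (um/min) for `"ballistic"`.
#' @param seed RNG seed.
#' @return data.frame with `track_id`, `t_min`, `x_um`, `y_um`, `z_um`.
#' @export
simulate_tracks <- function(n_tracks = 50, n_steps = 30, dt = 0.5, D = 10,
                            mode = c("brownian", "confined", "ballistic"),
                            radius = 10, speed = 10, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    pos <- matrix(0, n_steps + 1, 3)
    if (mode == "ballistic") {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2)) * speed * dt
      for (s in seq_len(n_steps)) pos[s + 1, ] <- pos[s, ] + u
    } else {
      sd_step <- sqrt(2 * D * dt)
      for (s in seq_len(n_steps)) {
        step <- stats::rnorm(3, sd = sd_step)
        p <- pos[s, ] + step
        if (mode == "confined") {
          r <- sqrt(sum(p^2))
          if (r > radius) p <- p * (2 * radius - r) / r  # reflect at the wall
        }
        pos[s + 1, ] <- p
      }
    }
    out[[i]] <- data.frame(track_id = i, t_min = (0:n_steps) * dt,
                           x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
  }
  do.call(rbind, out)
}

#' Motility coefficient of a single track
#'
#' Time-averaged mean squared displacement over the first third of lags,
#' fit linearly against lag time; the motility coefficient is the slope
#' divided by 6 (3D diffusion, MSD = 6 D t). The exponent of a log-log fit
#' flags sub-/superdiffusive motion (~1 diffusive, ~2 ballistic).
#'
#' @param track data.frame with `t_min`, `x_um`, `y_um`, `z_um` for one
#'   track (time strictly increasing).
#' @param min_duration minimum track duration (min); shorter tracks are
#'   excluded.
#' @return data.frame with `coefficient` (um^2/min), `duration`,
#'   `exponent`, `n_points`, and an `excluded` reason (`NA` if kept).
#' @export
motility_coefficient <- function(track, min_duration = 5) {
  t <- track$t_min
  if (is.unsorted(t, strictly = TRUE)) stop("track times must be strictly increasing")
  dur <- max(t) - min(t)
  if (dur < min_duration)
    return(data.frame(coefficient = NA_real_, duration = dur,
                      exponent = NA_real_, n_points = nrow(track),
                      excluded = sprintf("duration %.2f min < %g min",
                                         dur, min_duration)))
  pos <- as.matrix(track[, c("x_um", "y_um", "z_um")])
  n <- nrow(pos)
  max_lag <- max(1L, floor((n - 1) / 3))
  dt_med <- stats::median(diff(t))
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(k) {
    d <- pos[(k + 1):n, , drop = FALSE] - pos[1:(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, 0)
  lag_t <- lags * dt_med
  slope <- if (length(lags) == 1) msd / lag_t
  else stats::coef(stats::lm(msd ~ lag_t))[2]
  expo <- if (length(lags) >= 2 && all(msd > 0))
    stats::coef(stats::lm(log(msd) ~ log(lag_t)))[2]
  else NA_real_
  data.frame(coefficient = max(as.numeric(slope) / 6, 0), duration = dur,
             exponent = as.numeric(expo), n_points = n,
             excluded = NA_character_)
}

#' Motility coefficients for a set of tracks
#'
#' @param tracks data.frame with `track_id`, `t_min`, `x_um`, `y_um`,
#'   `z_um`.
#' @inheritParams motility_coefficient
#' @return data.frame, one row per track (see [motility_coefficient()]).
#' @export
motility_coefficients <- function(tracks, min_duration = 5) {
  ids <- unique(tracks$track_id)
  out <- do.call(rbind, lapply(ids, function(i)
    motility_coefficient(tracks[tracks$track_id == i, , drop = FALSE],
                         min_duration)))
  out$track_id <- ids
  out
}

# pooled (sqrt(elapsed time), displacement-from-start) scatter
displacement_scatter <- function(tracks) {
  ids <- unique(tracks$track_id)
  do.call(rbind, lapply(ids, function(i) {
    tr <- tracks[tracks$track_id == i, , drop = FALSE]
    t0 <- tr$t_min[1]
    p0 <- as.numeric(tr[1, c("x_um", "y_um", "z_um")])
    d <- sqrt((tr$x_um - p0[1])^2 + (tr$y_um - p0[2])^2 +
                (tr$z_um - p0[3])^2)
    data.frame(track_id = i, s = sqrt(tr$t_min - t0), disp = d)[-1, ]
  }))
}

#' Displacement versus root-time curve with bootstrap confidence band
#'
#' Pools per-track displacements from the track start against the square
#' root of elapsed time, fits a locally linear LOWESS curve (tricubic
#' weights), and derives a 95% confidence band by resampling *tracks* (not
#' points) with replacement. Freely diffusing cells give a straight line
#' through the origin on this axis; confined cells saturate. Diagnostics:
#' the origin-constrained slope, an intercept CI, and a curvature
#' statistic (slope over the upper half of the root-time range minus slope
#' over the lower half — negative values indicate saturation).
#'
#' @param tracks data.frame with `track_id`, `t_min`, `x_um`, `y_um`,
#'   `z_um`; at least 10 tracks.
#' @param bootstrap_n bootstrap resamples.
#' @param span LOWESS span (manual bandwidth).
#' @param grid_n evaluation points along root time.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @return list with `curve` (data.frame `s`, `fit`, `lo`, `hi`) and
#'   `diagnostics` (slope, intercept and curvature with CIs).
#' @export
displacement_curve <- function(tracks, bootstrap_n = 500, span = 0.75,
                               grid_n = 25, conf = 0.95, seed = 1) {
  ids <- unique(tracks$track_id)
  if (length(ids) < 10) stop("need at least 10 tracks")
  sc <- displacement_scatter(tracks)
  s_grid <- seq(min(sc$s), max(sc$s), length.out = grid_n)
  fit_fun <- function(dat) {
    fit <- stats::loess(disp ~ s, data = dat, degree = 1, span = span,
                        family = "gaussian")
    stats::predict(fit, data.frame(s = s_grid))
  }
  diag_fun <- function(dat) {
    lmfit <- stats::lm(disp ~ s, data = dat)
    mid <- stats::median(dat$s)
    lo_half <- dat[dat$s <= mid, ]; hi_half <- dat[dat$s > mid, ]
    slope_lo <- sum(lo_half$s * lo_half$disp) / sum(lo_half$s^2)
    slope_hi <- if (nrow(hi_half) > 1)
      as.numeric(stats::coef(stats::lm(disp ~ s, data = hi_half))[2])
    else slope_lo
    c(slope = sum(dat$s * dat$disp) / sum(dat$s^2),
      intercept = as.numeric(stats::coef(lmfit)[1]),
      curvature = slope_hi - slope_lo)
  }
  main_fit <- fit_fun(sc)
  main_diag <- diag_fun(sc)
  set.seed(seed)
  boot_fit <- matrix(NA_real_, bootstrap_n, grid_n)
  boot_diag <- matrix(NA_real_, bootstrap_n, 3)
  split_sc <- split(sc, sc$track_id)
  for (b in seq_len(bootstrap_n)) {
    pick <- sample(names(split_sc), length(split_sc), replace = TRUE)
    dat <- do.call(rbind, split_sc[pick])
    boot_fit[b, ] <- fit_fun(dat)
    boot_diag[b, ] <- diag_fun(dat)
  }
  a <- (1 - conf) / 2
  qs <- function(m) apply(m, 2, stats::quantile, probs = c(a, 1 - a),
                          na.rm = TRUE)
  band <- qs(boot_fit)
  dq <- qs(boot_diag)
  list(curve = data.frame(s = s_grid, fit = main_fit,
                          lo = band[1, ], hi = band[2, ]),
       diagnostics = data.frame(
         statistic = c("slope", "intercept", "curvature"),
         value = as.numeric(main_diag),
         lo = dq[1, ], hi = dq[2, ]))
}

#' Neighbor-density series of detected cells
#'
#' Per cell: the number of *other* cells within `radius`, divided by the
#' total number of cells detected at that time point; per time point: the
#' mean over cells. A lone cell contributes 0.
#'
#' @param positions data.frame with `t_min`, `x_um`, `y_um`, `z_um`.
#' @param radius neighbourhood radius (um).
#' @return data.frame with `t_min`, `n_cells`, `density` (`NA` with a
#'   warning for empty time points in a supplied factor level).
#' @export
cluster_density <- function(positions, radius = 100) {
  ts <- sort(unique(positions$t_min))
  out <- lapply(ts, function(tp) {
    p <- positions[positions$t_min == tp, c("x_um", "y_um", "z_um"),
                   drop = FALSE]
    n <- nrow(p)
    if (n == 0) {
      warning("empty time point at t = ", tp)
      return(data.frame(t_min = tp, n_cells = 0, density = NA_real_))
    }
    if (n == 1)
      return(data.frame(t_min = tp, n_cells = 1, density = 0))
    dm <- as.matrix(stats::dist(p))
    within <- rowSums(dm <= radius) - 1L
    data.frame(t_min = tp, n_cells = n, density = mean(within / n))
  })
  do.call(rbind, out)
}
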