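# End-to-end phantom study: standard-candle calibration on a spherical
# phantom, generalization test on a differently shaped (ellipsoid) phantom,
# and the comparison of illumination strategies.

#' Standard-candle calibration on a spherical phantom
#'
#' Runs the full calibration experiment the way the real one is performed:
#' seed standard candles in a spherical scattering sample, image each with
#' the spherical ray-optics model's power times a per-tile uniform
#' randomizing factor (0.5-2), featurize every candle (measured
#' brightness, field position, ray-distance histogram against the mapped
#' surface), and train the power-prediction network through the sinusoidal
#' EOM calibration.
#'
#' @param n_candles number of standard candles.
#' @param ls scattering mean free path (um), shared by the phantom and the
#'   ray-optics model.
#' @param radius calibration sphere radius (um).
#' @param brightness_cv lognormal CV of intrinsic candle brightness.
#' @param gain detector gain (brightness units at unit squared power).
#' @param seed RNG seed for candle placement, tile randomization, noise and
#'   training.
#' @param pupil a `lami_pupil` shared by the forward model and the
#'   ray-optics baseline.
#' @param config a `lami_predictor_config`; the default uses the annealed
#'   schedule suited to the power-space loss.
#' @param surface_spacing spacing of the picked surface points (um).
#' @return list with the phantom (`sample`), surface `map`, `lut`,
#'   acquisition `grid`, `records`, EOM `cal`, trained `predictor`, `gain`
#'   and `pupil`.
#' @export
calibrate_on_phantom <- function(n_candles = 10000, ls = 100, radius = 510,
                                 brightness_cv = 0.15, gain = 400, seed = 1,
                                 pupil = pupil_model(),
                                 config = predictor_config(
                                   lr = 3e-3, max_epochs = 4000,
                                   patience = 60, lr_decays = 5,
                                   seed = seed),
                                 surface_spacing = 12) {
  sample <- make_sample("sphere", ls = ls, center = c(0, 0, radius),
                        radius = radius)
  grid <- acquisition_grid()
  map <- build_surface(sample_surface_points(sample, spacing = surface_spacing))
  lut <- precompute_lut(sample, pupil)
  candles <- seed_candles(sample, n_candles, brightness_cv = brightness_cv,
                          seed = seed)
  policy <- make_lut_policy(lut, sample, amplitude = 1)
  records <- suppressWarnings(
    simulate_acquisition(sample, candles, grid, policy, pupil, gain = gain,
                         seed = seed + 1))
  cal <- synthetic_eom_calibration(p_max = 100)
  ts <- suppressWarnings(candle_training_set(map, records, cal))
  predictor <- train_predictor(ts$X, ts$voltage, cal, config)
  list(sample = sample, map = map, lut = lut, grid = grid,
       records = records, cal = cal, predictor = predictor, gain = gain,
       pupil = pupil)
}

#' Evaluate illumination strategies on a held-out phantom
#'
#' Seeds unit-brightness test candles in a differently shaped sample
#' (default: an ellipsoid) across the 0-300 um depth range of the mapped
#' cortical cap (surface-normal angle up to `max_angle`), and computes the
#' brightness each strategy would achieve at every candle:
#' \describe{
#'   \item{lami}{the trained predictor at target z-score 0.}
#'   \item{rayoptics}{the precomputed spherical model, which cannot know
#'     the sample's actual shape: it assumes the calibration sphere,
#'     tangent at the measured apex.}
#'   \item{constant}{depth-independent power.}
#' }
#' All strategies are normalized to aim for the training-mean brightness.
#' Reports the coefficient of variation of achieved brightness per strategy
#' and the per-candle relative error of the LAMI power against the
#' forward-model oracle.
#'
#' @param calib result of [calibrate_on_phantom()].
#' @param test_sample a `lami_sample`; default ellipsoid with semi-axes
#'   450 x 350 x 300 um and the calibration `ls`.
#' @param n_test number of test candles.
#' @param max_angle largest surface-normal angle included (degrees).
#' @param seed RNG seed.
#' @param surface_spacing surface point spacing for the test map (um).
#' @return list with per-candle `results` and a `summary` (median relative
#'   power error; CV of achieved brightness under lami / rayoptics /
#'   constant).
#' @export
evaluate_on_phantom <- function(calib, test_sample = NULL, n_test = 1500,
                                max_angle = 60, seed = 97,
                                surface_spacing = 12) {
  ls <- calib$sample$ls
  if (is.null(test_sample))
    test_sample <- make_sample("ellipsoid", ls = ls, center = c(0, 0, 300),
                               semiaxes = c(450, 350, 300))
  map <- build_surface(sample_surface_points(test_sample,
                                             spacing = surface_spacing))
  tc <- seed_candles(test_sample, n_test, brightness_cv = 0, seed = seed)
  ang <- sample_normal_angle(test_sample, tc$x, tc$y) * 180 / pi
  tc <- tc[ang <= max_angle, , drop = FALSE]
  loc <- locate_in_grid(calib$grid, tc$x, tc$y)
  pts <- as.matrix(tc[, c("x", "y", "z")])
  A <- attenuation_factor(test_sample, pts, calib$pupil)
  vig <- vignette_at(test_sample, loc$field_x, loc$field_y)
  depth <- tc$z - sample_surface_height(test_sample, tc$x, tc$y)
  f_target <- calib$predictor$mu[1]
  amp <- sqrt(f_target / calib$gain)
  # oracle: power that achieves the training-mean brightness at b = 1
  p_oracle <- amp / (sqrt(vig) * A)
  lami <- suppressWarnings(
    predict_power(calib$predictor, map, pts,
                  cbind(loc$field_x, loc$field_y), target = 0))
  # precomputed spherical model, tangent at the measured apex
  apex <- min(sample_surface_height(test_sample,
                                    test_sample$center[1],
                                    test_sample$center[2]))
  sphere_assumed <- make_sample("sphere", ls = ls,
                                center = c(test_sample$center[1],
                                           test_sample$center[2],
                                           apex + calib$lut$radius),
                                radius = calib$lut$radius)
  p_ray <- suppressWarnings(
    make_lut_policy(calib$lut, sphere_assumed, amplitude = amp)(pts))
  achieved <- function(p) calib$gain * vig * (p * A)^2
  results <- data.frame(
    x = tc$x, y = tc$y, z = tc$z, depth = depth, angle = ang[ang <= max_angle],
    p_oracle = p_oracle, p_lami = lami$power, p_ray = p_ray,
    f_lami = achieved(lami$power), f_ray = achieved(p_ray),
    f_const = achieved(amp))
  cv <- function(x) stats::sd(x) / mean(x)
  list(results = results,
       summary = list(
         median_rel_power_error =
           stats::median(abs(results$p_lami - p_oracle) / p_oracle),
         cv_lami = cv(results$f_lami),
         cv_rayoptics = cv(results$f_ray),
         cv_constant = cv(results$f_const)))
}
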