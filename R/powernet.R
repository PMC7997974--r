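#' Fit the sinusoidal EOM voltage-to-power calibration
#'
#' The electro-optic modulator's transmitted power as a function of input
#' voltage is well approximated by a sinusoid; this fits
#' `power(V) = a * (sin(w V + phi) - sin(phi))`, which builds in the
#' constraint `power(0) = 0` (0 V is off). The fitted curve must be
#' strictly increasing over the valid voltage range (full power at
#' `v_max`), or an error is raised.
#'
#' @param voltage measured voltages (V), at least 4 distinct values
#'   spanning the range.
#' @param power measured incident powers at those voltages.
#' @param v_max upper end of the valid voltage range (V).
#' @return object of class `lami_eom` with fields `a`, `w`, `phi`, `v_max`
#'   and the residual RMS of the fit.
#' @export
fit_eom_calibration <- function(voltage, power, v_max = 1.2) {
  if (length(unique(voltage)) < 4)
    stop("need at least 4 distinct voltages spanning the range")
  df <- data.frame(v = voltage, p = power)
  start <- list(a = max(power) / 2, w = pi / v_max, phi = -pi / 2)
  fit <- minpack.lm::nlsLM(p ~ a * (sin(w * v + phi) - sin(phi)),
                           data = df, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- as.list(stats::coef(fit))
  cal <- structure(list(a = cf$a, w = cf$w, phi = cf$phi, v_max = v_max,
                        rms = sqrt(mean(stats::resid(fit)^2))),
                   class = "lami_eom")
  vv <- seq(0, v_max, length.out = 200)
  if (any(diff(eom_power(cal, vv)) <= 0))
    stop("fitted sinusoid is not monotonically increasing on [0, v_max]")
  cal
}

#' Construct an EOM calibration analytically
#'
#' The physical transmission curve of an EOM between crossed polarizers is
#' `sin^2`, i.e. a sinusoid with offset equal to its amplitude; this helper
#' builds that curve directly with `power(v_max) = p_max`, for use in
#' simulated experiments.
#'
#' @param p_max power at full voltage (relative units).
#' @param v_max full-power voltage (V).
#' @return a `lami_eom`.
#' @export
synthetic_eom_calibration <- function(p_max = 100, v_max = 1.2) {
  structure(list(a = p_max / 2, w = pi / v_max, phi = -pi / 2,
                 v_max = v_max, rms = 0),
            class = "lami_eom")
}

#' Evaluate / invert an EOM calibration
#'
#' `eom_power` maps voltage to incident power; `eom_voltage` inverts it on
#' the monotonic branch (powers outside the attainable range clip to the
#' voltage range ends).
#'
#' @param cal a `lami_eom`.
#' @param voltage voltages (V).
#' @param power powers (same units as the calibration measurements).
#' @return numeric vector.
#' @export
eom_power <- function(cal, voltage) {
  cal$a * (sin(cal$w * voltage + cal$phi) - sin(cal$phi))
}

# derivative d power / d voltage, used in the training loss
eom_power_deriv <- function(cal, voltage) {
  cal$a * cal$w * cos(cal$w * voltage + cal$phi)
}

#' @rdname eom_power
#' @export
eom_voltage <- function(cal, power) {
  s <- clamp(power / cal$a + sin(cal$phi), -1, 1)
  v <- clamp((asin(s) - cal$phi) / cal$w, 0, cal$v_max)
  # one Newton polish removes the asin round-off near the branch ends
  dv <- eom_power_deriv(cal, v)
  ok <- abs(dv) > 1e-6 * abs(cal$a * cal$w)
  v[ok] <- v[ok] - (eom_power(cal, v[ok]) - power[ok]) / dv[ok]
  clamp(v, 0, cal$v_max)
}

#' Training configuration for the power predictor
#'
#' @param hidden hidden units of the single hidden layer.
#' @param dropout dropout probability during training.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param max_epochs upper bound on training epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param val_frac validation fraction.
#' @param lr_decays times the learning rate is annealed (by 3x, restoring
#'   the best weights) on a validation plateau before stopping for good.
#' @param seed RNG seed for split, initialization and dropout.
#' @return list of class `lami_predictor_config`.
#' @export
predictor_config <- function(hidden = 200, dropout = 0.5, batch_size = 1000,
                             lr = 1e-3, max_epochs = 800, patience = 10,
                             val_frac = 0.1, lr_decays = 3, seed = 1) {
  if (hidden < 1) stop("need at least one hidden unit")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(hidden = hidden, dropout = dropout, batch_size = batch_size,
                 lr = lr, max_epochs = max_epochs, patience = patience,
                 val_frac = val_frac, lr_decays = lr_decays, seed = seed),
            class = "lami_predictor_config")
}

#' Assemble a standard-candle training set from simulated records
#'
#' Featurizes each record (measured brightness, field XY, ray-distance
#' histogram at its focal position) and recovers the EOM voltage that was
#' applied from the recorded power through the calibration's inverse.
#'
#' @param map a `lami_surface` of the calibration sample.
#' @param records data.frame from [simulate_acquisition()].
#' @param cal a `lami_eom`.
#' @param config a `lami_shape_config`.
#' @return list with feature matrix `X` and target `voltage`.
#' @export
candle_training_set <- function(map, records, cal, config = shape_config()) {
  X <- featurize_points(map, as.matrix(records[, c("x", "y", "z")]),
                        records$brightness,
                        as.matrix(records[, c("field_x", "field_y")]), config)
  list(X = X, voltage = eom_voltage(cal, records$P0))
}

#' Train the excitation power predictor
#'
#' Fits a fully connected network (one hidden layer) mapping standardized
#' standard-candle features to EOM voltage. The network output is passed
#' through the sinusoidal calibration inside the loss, so the squared error
#' is taken in units of excitation *power*, not voltage: two calibrations
#' describing the same power curve therefore give identical losses.
#' Features are standardized element-wise by the training mean and standard
#' deviation; training stops when validation loss has not improved for
#' `patience` epochs.
#'
#' @param X numeric feature matrix (rows = candles), e.g. from
#'   [candle_training_set()]; needs >= 100 rows.
#' @param voltage applied EOM voltage per row.
#' @param cal a `lami_eom`.
#' @param config a `lami_predictor_config`.
#' @param tag laser/channel label stored with the model.
#' @return object of class `lami_predictor` (weights, standardizer,
#'   calibration, config, training history).
#' @export
train_predictor <- function(X, voltage, cal, config = predictor_config(),
                            tag = "laser1") {
  X <- as.matrix(X)
  if (nrow(X) < 100) stop("need at least 100 training records")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0] %||% which(sds == 0)
    stop("zero-variance feature column(s): ", paste(bad, collapse = ", "))
  }
  mu <- colMeans(X)
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  # the power curve is even about 0 V, so a pure power-space loss cannot
  # tell V from -V; a quadratic barrier keeps the network on the physical
  # branch [0, v_max] where the calibration is monotone
  barrier_w <- (cal$a * cal$w)^2
  loss_grad <- function(pred, target) {
    dp <- eom_power(cal, pred) - eom_power(cal, target)
    under <- pmin(pred, 0)
    over <- pmax(pred - cal$v_max, 0)
    list(loss = mean(dp^2) + barrier_w * mean(under^2 + over^2),
         dpred = 2 * dp * eom_power_deriv(cal, pred) +
           2 * barrier_w * (under + over))
  }
  # start the output on the monotonic branch of the calibration sinusoid
  fit <- nn_train(Xs, voltage, loss_grad,
                  hidden = config$hidden, dropout = config$dropout,
                  batch_size = config$batch_size, lr = config$lr,
                  max_epochs = config$max_epochs, patience = config$patience,
                  val_frac = config$val_frac, seed = config$seed,
                  out_bias = mean(voltage), out_sd = 0.01,
                  lr_decays = config$lr_decays, average_tail = TRUE)
  structure(list(par = fit$par, mu = mu, sd = sds, cal = cal,
                 config = config, tag = tag, history = fit$history,
                 best_epoch = fit$best_epoch),
            class = "lami_predictor")
}

#' @export
print.lami_predictor <- function(x, ...) {
  cat("<lami_predictor>", x$tag, "-", x$config$hidden, "hidden units;",
      length(x$history), "epochs\n")
  invisible(x)
}

# standardize a raw feature matrix with the predictor's training statistics
predictor_standardize <- function(predictor, X) {
  sweep(sweep(as.matrix(X), 2, predictor$mu), 2, predictor$sd, "/")
}

#' Predict excitation voltage and power at focal points
#'
#' Builds the shape features at each focal point, sets the brightness
#' element to the requested target (a z-score of the training brightness
#' distribution: 0 aims for the training-mean brightness, -1 for one
#' standard deviation dimmer), and runs the network deterministically
#' (dropout off). Voltages are clipped to the calibration range rather than
#' extrapolated.
#'
#' @param predictor a `lami_predictor`.
#' @param map a `lami_surface` of the sample being imaged.
#' @param points n x 3 matrix of focal points (um).
#' @param field_xy n x 2 matrix of positions within the field of view (um).
#' @param target target brightness z-score.
#' @param config a `lami_shape_config` (must match training).
#' @return data.frame with columns `voltage` (V) and `power` (calibration
#'   units).
#' @export
predict_power <- function(predictor, map, points, field_xy, target = 0,
                          config = shape_config()) {
  p <- as_point_matrix(points)
  bright_raw <- predictor$mu[1] + target * predictor$sd[1]
  X <- featurize_points(map, p, rep(bright_raw, nrow(p)),
                        matrix(field_xy, ncol = 2), config)
  Xs <- predictor_standardize(predictor, X)
  v <- clamp(nn_predict(predictor$par, Xs), 0, predictor$cal$v_max)
  data.frame(voltage = v, power = eom_power(predictor$cal, v))
}

#' Predict a modulation pattern for one field of view
#'
#' Evaluates the predictor at the nodes of a square grid spanning the field
#' (8 x 8 = 64 points by default) at plane depth `z`, returning relative
#' modulation values `voltage / v_max` in [0, 1] ready for the raster-scan
#' pattern engine. Grid nodes whose focal point is not featurizable
#' (outside the surface hull or above the surface) take the value of the
#' nearest featurizable node.
#'
#' @inheritParams predict_power
#' @param fov_origin XY position of the field corner (um).
#' @param z plane depth (um, absolute).
#' @param fov field size (um).
#' @param grid_n pattern nodes per side.
#' @return a `lami_pattern` (`grid_n` x `grid_n` matrix in [0, 1]).
#' @export
predict_grid <- function(predictor, map, fov_origin, z, fov = 220,
                         grid_n = 8, target = 0, config = shape_config()) {
  f <- (seq_len(grid_n) - 1) / (grid_n - 1) * fov
  nodes <- expand.grid(fx = f, fy = f)
  x <- fov_origin[1] + nodes$fx
  y <- fov_origin[2] + nodes$fy
  top <- surface_z(map, x, y)
  valid <- !is.na(top) & z > top
  if (!any(valid)) stop("entire field of view is outside the surface hull")
  pts <- cbind(x[valid], y[valid], z)
  pred <- predict_power(predictor, map, pts,
                        cbind(nodes$fx[valid], nodes$fy[valid]),
                        target = target, config = config)
  v <- numeric(nrow(nodes))
  v[valid] <- pred$voltage
  if (any(!valid)) {
    iv <- which(valid); ni <- which(!valid)
    for (i in ni) {
      d2 <- (x[iv] - x[i])^2 + (y[iv] - y[i])^2
      v[i] <- v[iv[which.min(d2)]]
    }
  }
  modulation_pattern(matrix(v / predictor$cal$v_max, grid_n, grid_n))
}

#' Serialize / restore a trained predictor as JSON
#'
#' @param predictor a `lami_predictor`.
#' @param path file path.
#' @return `read_predictor` returns a `lami_predictor`.
#' @export
write_predictor <- function(predictor, path) {
  obj <- list(tag = predictor$tag, mu = predictor$mu, sd = predictor$sd,
              cal = unclass(predictor$cal),
              config = unclass(predictor$config),
              W1 = predictor$par$W1, b1 = predictor$par$b1,
              W2 = predictor$par$W2, b2 = predictor$par$b2)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    par = list(W1 = o$W1, b1 = o$b1, W2 = matrix(o$W2, ncol = 1), b2 = o$b2),
    mu = o$mu, sd = o$sd,
    cal = structure(o$cal, class = "lami_eom"),
    config = structure(o$config, class = "lami_predictor_config"),
    tag = o$tag, history = numeric(0), best_epoch = NA),
    class = "lami_predictor")
}
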