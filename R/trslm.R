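#' Modulation pattern for the raster-scan pattern engine
#'
#' A low-resolution square grid of relative modulation values in [0, 1]
#' (fraction of the full-power voltage), pre-loaded into the time-realized
#' spatial light modulator and bilinearly interpolated across the field
#' during scanning.
#'
#' @param values square numeric matrix with entries in [0, 1] (rows map to
#'   the fast/X axis, columns to the slow/Y axis).
#' @return object of class `lami_pattern`.
#' @export
modulation_pattern <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("pattern grid must be square")
  if (any(values < -1e-9 | values > 1 + 1e-9))
    stop("pattern values must lie in [0, 1]")
  structure(clamp(values, 0, 1), class = c("lami_pattern", "matrix"))
}

#' Bilinear interpolation of a modulation pattern to pixel resolution
#'
#' Pattern nodes are placed at the corners and equal fractions of the
#' field, so node-aligned pixels reproduce the pattern exactly and the
#' interpolated image stays within the pattern's range. This provides the
#' smooth excitation gradient across the field rather than a blocky one.
#'
#' @param pattern a `lami_pattern` (or plain matrix).
#' @param shape output pixel grid `c(nx, ny)`, each >= 2.
#' @return numeric `nx x ny` matrix.
#' @export
interpolate_pattern <- function(pattern, shape) {
  m <- unclass(as.matrix(pattern))
  if (length(m) == 0) stop("empty pattern")
  if (any(shape < 2)) stop("pixel grid must be at least 2 x 2")
  n <- nrow(m)
  sample_at <- function(fx, fy) {
    # fx, fy in [0, 1]
    gx <- fx * (n - 1) + 1
    gy <- fy * (n - 1) + 1
    x0 <- pmin(floor(gx), n - 1); y0 <- pmin(floor(gy), n - 1)
    ax <- gx - x0; ay <- gy - y0
    m[cbind(x0, y0)] * (1 - ax) * (1 - ay) +
      m[cbind(x0 + 1, y0)] * ax * (1 - ay) +
      m[cbind(x0, y0 + 1)] * (1 - ax) * ay +
      m[cbind(x0 + 1, y0 + 1)] * ax * ay
  }
  fx <- (seq_len(shape[1]) - 1) / (shape[1] - 1)
  fy <- (seq_len(shape[2]) - 1) / (shape[2] - 1)
  g <- expand.grid(fx = fx, fy = fy)
  matrix(sample_at(g$fx, g$fy), shape[1], shape[2])
}

#' Raster-scan timing model
#'
#' X position follows the resonant scanner's sinusoidal sweep (one
#' unidirectional half-period per line, inverse-cosine mapping from elapsed
#' time), Y advances linearly line by line. The EOM command voltage is
#' updated every `update_interval` seconds, quantized to `dac_bits` bits of
#' the `v_full` full scale, and held between updates.
#'
#' @param line_period duration of one line (s).
#' @param n_lines lines per frame.
#' @param update_interval command update interval (s); default gives 32
#'   updates per line.
#' @param dac_bits DAC resolution in bits (`Inf` disables quantization).
#' @param v_full full-scale voltage (V).
#' @return object of class `lami_scan`.
#' @export
scan_model <- function(line_period = 63e-6, n_lines = 64,
                       update_interval = line_period / 32,
                       dac_bits = 12, v_full = 1.2) {
  if (update_interval <= 0) stop("update interval must be > 0")
  if (dac_bits < 1) stop("dac_bits must be >= 1")
  structure(list(line_period = line_period, n_lines = n_lines,
                 frame_period = line_period * n_lines,
                 update_interval = update_interval,
                 dac_bits = dac_bits, v_full = v_full),
            class = "lami_scan")
}

#' Scan position at an elapsed frame time
#'
#' @param t elapsed time within the frame (s), `0 <= t < frame period`.
#' @param scan a `lami_scan`.
#' @return matrix with columns `x`, `y` in [0, 1]^2.
#' @export
scan_position <- function(t, scan) {
  if (any(t < 0 | t >= scan$frame_period)) stop("t outside the frame period")
  line <- floor(t / scan$line_period)
  tl <- t - line * scan$line_period
  x <- (1 - cos(pi * tl / scan$line_period)) / 2
  y <- if (scan$n_lines > 1) line / (scan$n_lines - 1) else rep(0, length(t))
  cbind(x = x, y = y)
}

quantize_voltage <- function(v, scan) {
  if (!is.finite(scan$dac_bits)) return(v)
  step <- scan$v_full / 2^scan$dac_bits
  round(v / step) * step
}

#' Render the power actually applied by the pattern engine
#'
#' Simulates scanned frames: at every command update the controller
#' computes where the beam will be at the midpoint of the upcoming hold
#' interval, bilinearly interpolates the pre-loaded pattern there, and
#' drives the EOM with the quantized voltage, held until the next update.
#' Each image pixel receives the voltage held at the moment the resonant
#' sweep crosses it. The phase of the update clock relative to the
#' line-sync drifts from frame to frame (`phase_jitter`), and the rendered
#' power image averages `frames` frames — so finite update rates smear
#' structure along the fast (horizontal) axis while vertical structure
#' stays line-accurate, as in the physical device.
#'
#' @param pattern a `lami_pattern`.
#' @param scan a `lami_scan`; the rendered image has `n_pixels_x` pixels
#'   per line and one row of pixels per scan line.
#' @param cal optional `lami_eom`; `NULL` uses a linear (identity)
#'   voltage-to-power map normalized to full scale.
#' @param n_pixels_x pixels along the fast axis.
#' @param frames frames averaged in the rendered image.
#' @param phase_jitter randomize the update-clock phase per line and frame.
#' @param seed RNG seed for the phase jitter.
#' @return list with `voltage` (last frame) and `power` (frame-averaged)
#'   images (`n_pixels_x x n_lines`) and the command `trace` of the last
#'   frame (time, voltage).
#' @export
apply_pattern <- function(pattern, scan, cal = NULL, n_pixels_x = 64,
                          frames = 8, phase_jitter = TRUE, seed = 1) {
  ny <- scan$n_lines
  m <- unclass(as.matrix(pattern))
  n <- nrow(m)
  interp_at <- function(fx, fy) {
    gx <- fx * (n - 1) + 1; gy <- fy * (n - 1) + 1
    x0 <- pmin(floor(gx), n - 1); y0 <- pmin(floor(gy), n - 1)
    ax <- gx - x0; ay <- gy - y0
    m[cbind(x0, y0)] * (1 - ax) * (1 - ay) +
      m[cbind(x0 + 1, y0)] * ax * (1 - ay) +
      m[cbind(x0, y0 + 1)] * (1 - ax) * ay +
      m[cbind(x0 + 1, y0 + 1)] * ax * ay
  }
  to_power <- function(v) if (is.null(cal)) v / scan$v_full
  else eom_power(cal, v)
  set.seed(seed)
  xs <- (seq_len(n_pixels_x) - 0.5) / n_pixels_x
  # time at which the sweep crosses each pixel center
  t_cross <- scan$line_period / pi * acos(1 - 2 * xs)
  dt <- scan$update_interval
  power_acc <- matrix(0, n_pixels_x, ny)
  volt <- matrix(0, n_pixels_x, ny)
  trace_t <- c(); trace_v <- c()
  for (fr in seq_len(frames)) {
    last <- fr == frames
    for (line in seq_len(ny) - 1L) {
      fy <- if (ny > 1) line / (ny - 1) else 0
      phase <- if (phase_jitter) stats::runif(1, 0, dt) else 0
      t_up <- seq(phase - dt, scan$line_period - 1e-12, by = dt)
      # command the pattern value at the midpoint of the hold interval
      t_mid <- clamp(t_up + dt / 2, 0, scan$line_period)
      fx_mid <- (1 - cos(pi * t_mid / scan$line_period)) / 2
      v_up <- quantize_voltage(interp_at(fx_mid, rep(fy, length(t_mid))) *
                                 scan$v_full, scan)
      held <- pmax(findInterval(t_cross, t_up), 1L)
      vline <- v_up[held]
      power_acc[, line + 1L] <- power_acc[, line + 1L] + to_power(vline)
      if (last) {
        volt[, line + 1L] <- vline
        keep <- t_up >= 0
        trace_t <- c(trace_t, t_up[keep] + line * scan$line_period)
        trace_v <- c(trace_v, v_up[keep])
      }
    }
  }
  list(voltage = volt, power = power_acc / frames,
       trace = data.frame(t = trace_t, voltage = trace_v))
}
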