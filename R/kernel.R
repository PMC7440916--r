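# Ground-truth linear space-time kernels (Gabor envelopes with an
# optional space-time tilt that makes the kernel inseparable and hence
# direction selective).

#' Ground-truth spatiotemporal kernel
#'
#' The kernel is a Gaussian-windowed carrier,
#' `K(x, t) = A * exp(-x^2 / 2*sigma_x^2 - (t - t_center)^2 / 2*sigma_t^2)
#'             * cos(2*pi*(sf_cpd*x + tilt*(t - t_center)) + phase)`,
#' with `x` in degrees and lag `t` in ms.  `tilt` (cycles/ms) slants the
#' carrier in space-time: `tilt = 0` gives a separable (space profile x
#' time profile) kernel with zero predicted direction selectivity, and
#' increasing `|tilt|` increases the predicted direction selectivity.
#' The implied preferred velocity is `-tilt / sf_cpd` deg/ms.
#'
#' @param sigma_x,sigma_t Envelope widths (degrees, ms); must be > 0.
#' @param sf_cpd Carrier spatial frequency, cycles/degree.
#' @param tilt Space-time tilt of the carrier, cycles/ms.
#' @param phase Carrier phase, radians.
#' @param t_center Temporal envelope center, ms.
#' @param amplitude Peak kernel weight, mV per unit contrast per sample.
#' @param space_axis Position axis, degrees (monotone).
#' @param lag_axis Lag axis, ms (monotone, non-negative).
#' @return A `kernel_strf`: list with `weights` (positions x lags),
#'   `space_axis_deg`, `lag_axis_ms` and the generating parameters.
#' @export
make_ground_truth_kernel <- function(sigma_x, sigma_t, sf_cpd = 0.08,
                                     tilt = 0, phase = 0, t_center = 120,
                                     amplitude = 1,
                                     space_axis = seq(-23.25, 23.25, by = 3.1),
                                     lag_axis = seq(0, 400, by = 1)) {
  check_scalar(sigma_x, "sigma_x", positive = TRUE)
  check_scalar(sigma_t, "sigma_t", positive = TRUE)
  if (any(lag_axis < 0))
    stop_invalid("`lag_axis` must not contain negative lags")
  if (is.unsorted(space_axis) || is.unsorted(lag_axis))
    stop_invalid("axes must be monotone increasing")
  env <- outer(exp(-space_axis^2 / (2 * sigma_x^2)),
               exp(-(lag_axis - t_center)^2 / (2 * sigma_t^2)))
  carrier <- cos(2 * pi * outer(sf_cpd * space_axis,
                                tilt * (lag_axis - t_center), "+") + phase)
  structure(list(
    weights = amplitude * env * carrier,
    space_axis_deg = space_axis,
    lag_axis_ms = lag_axis,
    sigma_x = sigma_x, sigma_t = sigma_t, sf_cpd = sf_cpd, tilt = tilt,
    phase = phase, t_center = t_center, amplitude = amplitude
  ), class = "kernel_strf")
}

#' @export
print.kernel_strf <- function(x, ...) {
  cat(sprintf(
    "<kernel_strf> %d positions x %d lags; tilt %g cycles/ms, t_center %g ms\n",
    nrow(x$weights), ncol(x$weights), x$tilt, x$t_center))
  invisible(x)
}

# Resample kernel lags onto the simulation grid (linear interpolation).
# Weights are defined per lag sample of the kernel's own grid, so they
# are rescaled by the spacing ratio to conserve the summed drive.
kernel_on_grid <- function(kernel, dt_ms) {
  base <- mean(diff(kernel$lag_axis_ms))
  lags <- seq(min(kernel$lag_axis_ms), max(kernel$lag_axis_ms), by = dt_ms)
  w <- t(apply(kernel$weights, 1, function(row)
    stats::approx(kernel$lag_axis_ms, row, xout = lags, rule = 2)$y))
  list(weights = w * (dt_ms / base), lag_ms = lags)
}

#' Expected raw-correlation image of a kernel
#'
#' Reverse correlation of responses to a frame-wise stimulus does not
#' recover the kernel itself but the kernel blurred in time by the
#' stimulus frame: exactly by the frame autocorrelation (a centred
#' triangle of half-width `frame_ms` for zero-order-hold frames), or
#' approximately by a causal `frame_ms` boxcar.  This helper computes
#' that expectation on the STRF pixel grid, for use as an oracle when
#' validating the estimator.
#'
#' @param kernel A `kernel_strf` on a 1 ms lag grid.
#' @param frame_ms Stimulus frame duration, ms.
#' @param lag_bin_ms STRF pixel size along the lag axis, ms.
#' @param max_lag_ms Largest lag, ms.
#' @param shape `"triangle"` (exact) or `"boxcar"` (approximate).
#' @return A `strf_map` holding the blurred, binned kernel (arbitrary
#'   units).
#' @export
blur_kernel <- function(kernel, frame_ms = 100, lag_bin_ms = 10,
                        max_lag_ms = 400,
                        shape = c("triangle", "boxcar")) {
  shape <- match.arg(shape)
  stopifnot(inherits(kernel, "kernel_strf"))
  kg <- kernel_on_grid(kernel, 1)
  f <- round(frame_ms)
  if (shape == "triangle") {
    off <- -(f - 1):(f - 1)
    wts <- (f - abs(off)) / f^2
  } else {
    off <- 0:(f - 1)
    wts <- rep(1 / f, f)
  }
  n_lag <- round(max_lag_ms)
  blur <- t(apply(kg$weights, 1, function(row) {
    out <- numeric(n_lag)
    for (j in seq_along(off)) {
      src <- seq_len(n_lag) - off[j]
      ok <- src >= 1 & src <= length(row)
      out[ok] <- out[ok] + wts[j] * row[src[ok]]
    }
    out
  }))
  fac <- round(lag_bin_ms)
  n_bins <- floor(n_lag / fac)
  idx <- rep(seq_len(n_bins), each = fac)
  binned <- t(apply(blur[, seq_len(n_bins * fac), drop = FALSE], 1,
                    function(r) tapply(r, idx, mean)))
  new_strf_map(binned, (seq_len(n_bins) - 0.5) * lag_bin_ms,
               kernel$space_axis_deg, FALSE)
}
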