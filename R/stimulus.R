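# Stimulus generation: drifting gratings and sparse 1-D bar noise.
#
# Stimuli are one-dimensional in space: bars parallel to the cell's
# preferred orientation, indexed by position along the orthogonal axis.

new_stimulus_movie <- function(contrast, frame_ms, bar_width_deg, kind,
                               direction_deg = NA_real_, tf_hz = NA_real_,
                               sf_cpd = NA_real_) {
  n_pos <- nrow(contrast)
  structure(list(
    contrast = contrast,
    frame_ms = frame_ms,
    bar_width_deg = bar_width_deg,
    space_axis_deg = (seq_len(n_pos) - (n_pos + 1) / 2) * bar_width_deg,
    kind = kind,
    direction_deg = direction_deg,
    tf_hz = tf_hz,
    sf_cpd = sf_cpd
  ), class = "stimulus_movie")
}

#' @export
print.stimulus_movie <- function(x, ...) {
  cat(sprintf("<stimulus_movie> %s: %d positions x %d frames (%g ms/frame, %g deg bars)\n",
              x$kind, nrow(x$contrast), ncol(x$contrast), x$frame_ms,
              x$bar_width_deg))
  invisible(x)
}

#' Drifting sinusoidal grating as a 1-D space x time contrast movie
#'
#' Contrast at bar position `x` (degrees) and frame time `t` (seconds) is
#' `cos(2*pi*(sf*x - s*tf*t))`, where `s = +1` for directions in
#' `[0, 180)` degrees and `s = -1` for the opposite motions, so the two
#' opposite directions differ only in the sign of the temporal term.
#'
#' @param direction_deg Direction of motion in degrees; only the
#'   half-plane (the sign of motion along the bar-position axis) matters
#'   for a 1-D stimulus.
#' @param tf_hz Temporal (drift) frequency in Hz; experiments here use
#'   2-8 Hz, typically 4 Hz.
#' @param sf_cpd Spatial frequency in cycles per degree (default 0.08).
#' @param duration_s Stimulus duration in seconds.
#' @param n_positions Number of bar positions.
#' @param bar_width_deg Bar width (position spacing) in degrees.
#' @param frame_ms Frame duration in ms.
#' @return A `stimulus_movie` with `kind = "grating"`.
#' @examples
#' g <- make_grating_stimulus(0, tf_hz = 4, duration_s = 1)
#' range(g$contrast)
#' @export
make_grating_stimulus <- function(direction_deg = 0, tf_hz = 4,
                                  sf_cpd = 0.08, duration_s = 4,
                                  n_positions = 16, bar_width_deg = 3.1,
                                  frame_ms = 10) {
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(frame_ms, "frame_ms", positive = TRUE)
  if (!is.numeric(n_positions) || n_positions < 1)
    stop_invalid("`n_positions` must be a positive integer")
  n_frames <- round(duration_s * 1000 / frame_ms)
  if (n_frames < 1) stop_invalid("duration shorter than one frame")
  s <- if (direction_deg %% 360 < 180) 1 else -1
  x <- (seq_len(n_positions) - (n_positions + 1) / 2) * bar_width_deg
  t_s <- (seq_len(n_frames) - 1) * frame_ms / 1000
  contrast <- cos(2 * pi * outer(sf_cpd * x, -s * tf_hz * t_s, "+"))
  new_stimulus_movie(contrast, frame_ms, bar_width_deg, "grating",
                     direction_deg = direction_deg %% 360,
                     tf_hz = tf_hz, sf_cpd = sf_cpd)
}

#' Sparse 1-D bar noise stimulus
#'
#' Each bar is independently black (contrast -1), white (+1) or gray (0)
#' on every frame; defaults follow the classical sparse-noise protocol
#' (10% black, 10% white, 100 ms frames).
#'
#' @param n_positions Number of bar positions.
#' @param duration_s Duration in seconds.
#' @param frame_ms Frame duration in ms (default 100).
#' @param p_black,p_white Per-bar probabilities of black / white.
#' @param bar_width_deg Bar width in degrees.
#' @param seed Integer seed; identical seeds give identical movies.
#' @return A `stimulus_movie` with `kind = "sparse_noise"`.
#' @export
make_sparse_noise <- function(n_positions = 16, duration_s = 600,
                              frame_ms = 100, p_black = 0.1,
                              p_white = 0.1, bar_width_deg = 3.1,
                              seed = NULL) {
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(frame_ms, "frame_ms", positive = TRUE)
  for (p in c(p_black, p_white))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop_invalid("probabilities must lie in [0, 1]")
  if (p_black + p_white > 1)
    stop_invalid("p_black + p_white must be <= 1")
  n_frames <- round(duration_s * 1000 / frame_ms)
  contrast <- with_seed(seed, {
    vals <- sample(c(-1, 0, 1), n_positions * n_frames, replace = TRUE,
                   prob = c(p_black, 1 - p_black - p_white, p_white))
    matrix(vals, nrow = n_positions, ncol = n_frames)
  })
  new_stimulus_movie(contrast, frame_ms, bar_width_deg, "sparse_noise")
}

# Zero-order-hold upsampling of a frame movie to the Vm sample grid.
upsample_stimulus <- function(stimulus, dt_ms) {
  rep_per <- stimulus$frame_ms / dt_ms
  if (abs(rep_per - round(rep_per)) > 1e-9)
    stop_invalid("frame_ms must be an integer multiple of dt_ms")
  rep_per <- as.integer(round(rep_per))
  idx <- rep(seq_len(ncol(stimulus$contrast)), each = rep_per)
  stimulus$contrast[, idx, drop = FALSE]
}
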