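# Grating-response analysis: F0/F1 decomposition, simple/complex
# classification, double-Gaussian direction tuning fits, direction
# selectivity index, responsiveness gating, and response latency.

#' F0 and F1 components of a periodic response
#'
#' The response (Vm or a binned firing-rate trace) is truncated to the
#' largest whole number of stimulus cycles; `F0` is the mean over that
#' window and `F1` is the amplitude of the Fourier component at the
#' stimulus temporal frequency (`2 * |sum x * exp(-2i*pi*f*t)| / N`).
#'
#' @param x Numeric response samples, or a `vm_trace`.
#' @param tf_hz Stimulus temporal frequency, Hz.
#' @param dt_ms Sampling interval (ignored when `x` is a `vm_trace`).
#' @return List with `F0`, `F1`, `tf_hz`, `n_cycles`.
#' @export
cycle_fourier <- function(x, tf_hz, dt_ms = NULL) {
  if (inherits(x, "vm_trace")) { dt_ms <- x$dt_ms; x <- x$samples }
  check_scalar(tf_hz, "tf_hz", positive = TRUE)
  check_scalar(dt_ms, "dt_ms", positive = TRUE)
  period_ms <- 1000 / tf_hz
  n_cycles <- floor(length(x) * dt_ms / period_ms)
  if (n_cycles < 1) stop_invalid("window shorter than one stimulus cycle")
  n <- round(n_cycles * period_ms / dt_ms)
  x <- x[seq_len(n)]
  t_s <- (seq_len(n) - 1) * dt_ms / 1000
  coef <- sum(x * exp(-2i * pi * tf_hz * t_s))
  list(F0 = mean(x), F1 = 2 * Mod(coef) / n, tf_hz = tf_hz,
       n_cycles = n_cycles)
}

#' Simple/complex classification from modulation ratios
#'
#' Spiking cells are simple when the spike modulation ratio (F1/F0) is
#' at least 1.0; cells without sufficient spikes are simple when the Vm
#' modulation ratio exceeds 0.5.
#'
#' @param spike_mod_ratio Spike F1/F0 (may be `NA` when `has_spikes`
#'   is `FALSE`).
#' @param vm_mod_ratio Vm F1/F0.
#' @param has_spikes Did the cell fire enough spikes to classify on
#'   spiking?
#' @return `"simple"` or `"complex"`.
#' @export
classify_simple_complex <- function(spike_mod_ratio, vm_mod_ratio,
                                    has_spikes = TRUE) {
  if (has_spikes) {
    if (!is.finite(spike_mod_ratio))
      stop_invalid("modulation ratio undefined (F0 = 0?)")
    if (spike_mod_ratio >= 1.0) "simple" else "complex"
  } else {
    if (!is.finite(vm_mod_ratio))
      stop_invalid("modulation ratio undefined (F0 = 0?)")
    if (vm_mod_ratio > 0.5) "simple" else "complex"
  }
}

# Wrapped angular difference in degrees, in [0, 180].
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Double-Gaussian fit of a direction tuning curve
#'
#' Fits `R(theta) = R0 + Rp*exp(-d(theta, theta_p)^2 / 2*sigma^2) +
#' Rn*exp(-d(theta, theta_p + 180)^2 / 2*sigma^2)` with a shared width
#' and wrapped angular distance `d`, by least squares with multi-start
#' over the sampled directions for `theta_p`.
#'
#' @param directions_deg Sampled directions, degrees (>= 6 distinct).
#' @param resp Mean response per direction.
#' @return List with `R0`, `Rp`, `Rn`, `theta_p` (in \[0, 360)),
#'   `sigma`, `sse`, `converged`; on failure the empirical-peak fallback
#'   is returned with `converged = FALSE`.
#' @export
fit_double_gaussian <- function(directions_deg, resp) {
  if (length(directions_deg) != length(resp))
    stop_invalid("directions and responses must have equal length")
  if (length(unique(directions_deg %% 360)) < 6)
    stop_invalid("need >= 6 distinct directions")
  model <- function(p, th) {
    p[1] + p[2] * exp(-angle_diff(th, p[4])^2 / (2 * p[5]^2)) +
      p[3] * exp(-angle_diff(th, p[4] + 180)^2 / (2 * p[5]^2))
  }
  sse <- function(p) sum((resp - model(p, directions_deg))^2)
  best <- NULL
  r0_init <- min(resp)
  amp <- max(resp) - min(resp)
  for (th0 in unique(directions_deg %% 360)) {
    p0 <- c(r0_init, amp, amp / 2, th0, 30)
    fit <- try(stats::optim(p0, sse, method = "L-BFGS-B",
                            lower = c(-Inf, 0, 0, th0 - 90, 5),
                            upper = c(Inf, Inf, Inf, th0 + 90, 180)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    th_peak <- directions_deg[which.max(resp)]
    return(list(R0 = 0, Rp = max(resp), Rn = 0, theta_p = th_peak %% 360,
                sigma = 30, sse = NA_real_, converged = FALSE))
  }
  p <- best$par
  # orient so Rp is the larger lobe
  if (p[3] > p[2]) {
    p[c(2, 3)] <- p[c(3, 2)]
    p[4] <- p[4] + 180
  }
  list(R0 = p[1], Rp = p[2], Rn = p[3], theta_p = p[4] %% 360,
       sigma = p[5], sse = best$value, converged = best$convergence == 0)
}

#' Direction selectivity index
#'
#' `DSI = (Rp - Rn) / Rp` with the null response rectified at zero, so
#' the index lies in \[0, 1\].  `Rp <= 0` leaves the index undefined
#' (`NA`); such cells are excluded from group analyses.
#'
#' @param Rp Response to the preferred direction (> 0).
#' @param Rn Response to the opposite direction.
#' @export
dsi <- function(Rp, Rn) {
  if (!is.finite(Rp) || Rp <= 0) return(NA_real_)
  Rn <- max(Rn, 0)
  (Rp - Rn) / Rp
}

#' Direction selectivity from a sampled tuning curve
#'
#' The double-Gaussian fit is used only to locate the preferred angle;
#' `Rp` and `Rn` are the empirical responses at the sampled direction
#' nearest `theta_p` and at its opposite, which avoids fit-shape
#' artifacts in the index.
#'
#' @inheritParams fit_double_gaussian
#' @return List with `dsi`, `Rp`, `Rn`, `theta_p` and the `fit`.
#' @export
dsi_from_curve <- function(directions_deg, resp) {
  fit <- fit_double_gaussian(directions_deg, resp)
  i_p <- which.min(angle_diff(directions_deg, fit$theta_p))
  i_n <- which.min(angle_diff(directions_deg, fit$theta_p + 180))
  Rp <- resp[i_p]
  Rn <- resp[i_n]
  list(dsi = dsi(Rp, Rn), Rp = Rp, Rn = Rn,
       theta_p = directions_deg[i_p] %% 360, fit = fit)
}

#' Responsiveness gate: one-way ANOVA across stimuli
#'
#' Cells whose trial responses do not vary significantly across stimuli
#' (p >= 0.05) are excluded from direction-selectivity analyses.
#'
#' @param trial_responses_by_stimulus List of numeric vectors, one per
#'   stimulus, each holding per-trial responses (>= 2 trials each).
#' @return The ANOVA p-value (1 when there is no variance at all).
#' @export
responsiveness_anova <- function(trial_responses_by_stimulus) {
  k <- length(trial_responses_by_stimulus)
  if (k < 2) stop_invalid("need >= 2 stimuli")
  if (any(lengths(trial_responses_by_stimulus) < 2))
    stop_invalid("need >= 2 trials per stimulus")
  y <- unlist(trial_responses_by_stimulus, use.names = FALSE)
  g <- factor(rep(seq_len(k), lengths(trial_responses_by_stimulus)))
  if (stats::var(y) == 0) return(1)
  tab <- stats::anova(stats::aov(y ~ g))
  p <- tab[["Pr(>F)"]][1]
  if (!is.finite(p)) 1 else p
}

#' Vm response latency
#'
#' First post-onset time at which the (spike-filtered) Vm exceeds the
#' pre-stimulus baseline mean by `k` baseline standard deviations.
#'
#' @param vm A `vm_trace` (spike-filtered).
#' @param baseline_mean,baseline_sd Pre-stimulus baseline statistics.
#' @param k Threshold in baseline SDs (default 6).
#' @param stim_onset_ms Stimulus onset, ms.
#' @return Latency from onset in ms, or `NA` if never reached.
#' @export
response_latency <- function(vm, baseline_mean, baseline_sd, k = 6,
                             stim_onset_ms = 0) {
  stopifnot(inherits(vm, "vm_trace"))
  if (!is.finite(baseline_sd) || baseline_sd <= 0)
    stop_invalid("baseline SD must be > 0")
  t <- vm_times_ms(vm)
  post <- which(t >= stim_onset_ms &
                  vm$samples - baseline_mean >= k * baseline_sd)
  if (!length(post)) return(NA_real_)
  t[post[1]] - stim_onset_ms
}

#' Firing-rate trace from spike times
#'
#' Bins spikes on the same grid as a Vm trace so that spiking responses
#' can be Fourier-analysed like Vm responses.
#'
#' @param spikes A `spike_train`.
#' @param t0_ms Trace start, ms.
#' @param duration_ms Trace duration, ms.
#' @param bin_ms Bin width, ms.
#' @return List with `rate_hz` (per bin) and `bin_ms`.
#' @export
rate_from_spikes <- function(spikes, t0_ms, duration_ms, bin_ms = 10) {
  stopifnot(inherits(spikes, "spike_train"))
  n_bins <- floor(duration_ms / bin_ms)
  tm <- spikes$times_ms
  tm <- tm[tm >= t0_ms & tm < t0_ms + n_bins * bin_ms]
  counts <- tabulate(floor((tm - t0_ms) / bin_ms) + 1L, nbins = n_bins)
  list(rate_hz = counts / (bin_ms / 1000), bin_ms = bin_ms)
}
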