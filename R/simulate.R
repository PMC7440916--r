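# Forward linear-nonlinear simulation: stimulus -> subthreshold Vm ->
# spikes (Bernoulli thinning of a rectified power-law rate).

new_vm_trace <- function(samples, dt_ms, t0_ms = 0) {
  structure(list(samples = as.numeric(samples), dt_ms = dt_ms,
                 t0_ms = t0_ms), class = "vm_trace")
}

#' @export
print.vm_trace <- function(x, ...) {
  cat(sprintf("<vm_trace> %d samples @ %g ms (%.1f s), range [%.1f, %.1f] mV\n",
              length(x$samples), x$dt_ms,
              length(x$samples) * x$dt_ms / 1000,
              min(x$samples), max(x$samples)))
  invisible(x)
}

vm_times_ms <- function(vm) vm$t0_ms + (seq_along(vm$samples) - 1) * vm$dt_ms

as_vm_trace <- function(x, dt_ms = NULL) {
  if (inherits(x, "vm_trace")) return(x)
  if (is.null(dt_ms)) stop_invalid("`dt_ms` required for a bare numeric trace")
  new_vm_trace(x, dt_ms)
}

new_spike_train <- function(times_ms) {
  times_ms <- as.numeric(times_ms)
  if (is.unsorted(times_ms, strictly = TRUE) && length(times_ms) > 1)
    stop_invalid("spike times must be strictly increasing")
  structure(list(times_ms = times_ms), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes\n", length(x$times_ms)))
  invisible(x)
}

#' Simulate subthreshold membrane potential from a linear kernel
#'
#' Discrete convolution of the stimulus with the kernel plus additive
#' Gaussian noise:
#' `Vm(t) = baseline + sum_x sum_tau K(x, tau) * contrast(x, t - tau) + noise`.
#' The stimulus is upsampled to the Vm sampling grid by zero-order hold;
#' the kernel is resampled onto the same lag grid.  With `noise_sd = 0`
#' the output is exactly linear in the stimulus.
#'
#' @param stimulus A `stimulus_movie`.
#' @param kernel A `kernel_strf` on the same space axis as the stimulus.
#' @param noise_sd Additive Gaussian noise SD, mV.
#' @param baseline_mV Resting potential added to the drive.
#' @param dt_ms Vm sampling interval, ms (frame_ms must be a multiple).
#' @param seed Integer seed for the noise.
#' @return A `vm_trace`.
#' @export
simulate_vm <- function(stimulus, kernel, noise_sd = 2, baseline_mV = -70,
                        dt_ms = 1, seed = NULL) {
  stopifnot(inherits(stimulus, "stimulus_movie"),
            inherits(kernel, "kernel_strf"))
  if (nrow(stimulus$contrast) != nrow(kernel$weights))
    stop_invalid("stimulus and kernel position axes differ")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  s <- upsample_stimulus(stimulus, dt_ms)
  kg <- kernel_on_grid(kernel, dt_ms)
  n <- ncol(s)
  drive <- numeric(n)
  for (i in seq_len(nrow(s)))
    drive <- drive + conv_causal(s[i, ], kg$weights[i, ])
  # Band-limited noise: drawn on a 1 ms grid and interpolated to finer
  # sampling, emulating the limited bandwidth of recorded Vm noise
  # (synaptic fluctuations plus an anti-alias filtered amplifier).
  noise <- if (noise_sd > 0) with_seed(seed, {
    if (dt_ms >= 1) stats::rnorm(n, 0, noise_sd)
    else {
      t_ms <- (seq_len(n) - 1) * dt_ms
      grid <- seq(0, max(t_ms) + 1, by = 1)
      stats::approx(grid, stats::rnorm(length(grid), 0, noise_sd),
                    xout = t_ms)$y
    }
  }) else 0
  new_vm_trace(baseline_mV + drive + noise, dt_ms)
}

#' Generate spikes from subthreshold Vm via a rectified power law
#'
#' The instantaneous rate is `FR(V) = b * max(V - Vth, 0)^alpha` (Hz);
#' each sample spikes independently with probability `FR * dt` subject to
#' an absolute refractory period.
#'
#' @param vm_subthreshold A `vm_trace` (spike-free Vm).
#' @param vf_params List or `vf_transform` with fields `b`, `vth`,
#'   `alpha` (`vth` in the same units as the trace).
#' The instantaneous rate saturates at `rate_max` (default the
#' refractory-limited 1000/refractory_ms Hz), since no point process
#' with an absolute refractory period can exceed it anyway.
#'
#' @param refractory_ms Absolute refractory period, ms.
#' @param rate_max Saturation rate, Hz.
#' @param seed Integer seed.
#' @return A `spike_train`; times at the centre of the spiking sample.
#' @export
simulate_spikes <- function(vm_subthreshold, vf_params, refractory_ms = 2,
                            rate_max = NULL, seed = NULL) {
  vm <- vm_subthreshold
  stopifnot(inherits(vm, "vm_trace"))
  if (refractory_ms < 0) stop_invalid("`refractory_ms` must be >= 0")
  rate_max <- rate_max %||%
    (if (refractory_ms > 0) 1000 / refractory_ms else Inf)
  rate <- pmin(vf_rate(vf_params, vm$samples), rate_max)
  p <- rate * vm$dt_ms / 1000
  if (any(p > 1))
    stop_invalid("rate * dt exceeds 1 for some samples; reduce dt_ms")
  cand <- with_seed(seed, which(stats::runif(length(p)) < p))
  times <- vm_times_ms(vm)[cand]
  if (length(times) > 1 && refractory_ms > 0) {
    keep <- times[1]
    last <- times[1]
    for (t in times[-1]) {
      if (t - last >= refractory_ms) {
        keep <- c(keep, t)
        last <- t
      }
    }
    times <- keep
  }
  new_spike_train(times)
}

# Rectified power-law rate; accepts a vf_transform or a bare list.
vf_rate <- function(vf, v) {
  b <- vf$b %||% vf[["b"]]
  vth <- vf$vth %||% vf[["Vth"]]
  alpha <- vf$alpha
  if (is.null(b) || is.null(vth) || is.null(alpha))
    stop_invalid("vf parameters must supply b, vth and alpha")
  b * pmax(v - vth, 0)^alpha
}

`%||%` <- function(a, b) if (is.null(a)) b else a
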