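# Spike-waveform excitability metrics: maximal rate of rise, spike kink
# (threshold) voltage, full width at half height, and F-I curve slopes.
#
# dV/dt is always the successive-sample difference divided by the
# sampling interval; metrics refer to the rising phase up to the peak.

#' Extract peak-aligned spike waveforms
#'
#' Cuts a window around every spike, aligned on the waveform peak (the
#' local maximum within 3 ms after the nominal spike time).  Spikes whose
#' window would overlap a trace edge are dropped with a warning, and by
#' default only isolated spikes (no neighbour within `isolated_ms`) are
#' used, since overlapping waveforms within a burst sum and corrupt
#' shape metrics.
#'
#' @param vm A `vm_trace` containing action potentials.
#' @param spikes A `spike_train`.
#' @param pre_ms,post_ms Window before/after the peak, ms.
#' @param isolated_ms Minimum distance to the nearest neighbouring
#'   spike; `NULL` disables the isolation filter.
#' @return List with `waveforms` (matrix, one row per spike), `mean`
#'   (mean waveform), `peak_index` (shared peak sample) and `dt_ms`.
#' @export
extract_spike_waveforms <- function(vm, spikes, pre_ms = 5, post_ms = 10,
                                    isolated_ms = 5) {
  stopifnot(inherits(vm, "vm_trace"), inherits(spikes, "spike_train"))
  dt <- vm$dt_ms
  n <- length(vm$samples)
  npre <- round(pre_ms / dt)
  npost <- round(post_ms / dt)
  search <- round(3 / dt)
  use <- spikes$times_ms
  if (!is.null(isolated_ms) && length(use) > 1) {
    gap_ok <- c(diff(use) >= isolated_ms, TRUE) &
      c(TRUE, diff(use) >= isolated_ms)
    use <- use[gap_ok]
  }
  rows <- list()
  dropped <- 0L
  for (t_sp in use) {
    i0 <- round((t_sp - vm$t0_ms) / dt) + 1L
    hi <- min(n, i0 + search)
    if (i0 < 1 || i0 > n) { dropped <- dropped + 1L; next }
    pk <- i0 - 1L + which.max(vm$samples[i0:hi])
    if (pk - npre < 1 || pk + npost > n) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- vm$samples[(pk - npre):(pk + npost)]
  }
  if (dropped > 0)
    warning(sprintf("%d spike(s) dropped (window overlaps trace edge)",
                    dropped))
  wf <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), nrow = 0, ncol = npre + npost + 1)
  list(waveforms = wf,
       mean = if (nrow(wf)) colMeans(wf) else numeric(0),
       peak_index = npre + 1L, dt_ms = dt)
}

#' Maximal rate of rise of a spike waveform
#'
#' Maximum of the discrete derivative over the rising phase (up to the
#' waveform peak), in mV/ms.
#'
#' @param waveform Numeric voltage waveform (mV).
#' @param dt_ms Sampling interval, ms.
#' @export
max_dvdt <- function(waveform, dt_ms) {
  if (length(waveform) < 2) stop_invalid("waveform needs >= 2 samples")
  pk <- which.max(waveform)
  d <- diff(waveform) / dt_ms
  max(d[seq_len(max(pk - 1L, 1L))])
}

#' Spike kink (threshold) voltage
#'
#' The take-off voltage: where dV/dt exceeds `frac` (default 0.033) of
#' its maximum.  The crossing is located by scanning backward from the
#' peak (bounded at `search_ms` before it) to the last sample at which
#' dV/dt was still below the criterion; the kink is the voltage of the
#' next sample.  For a waveform whose rate of rise grows monotonically
#' this equals the first forward crossing; the backward search makes
#' the measure robust to brief pre-spike depolarisations.
#'
#' @param waveform Numeric voltage waveform (mV).
#' @param dt_ms Sampling interval, ms.
#' @param frac Fraction of the maximal dV/dt defining take-off.
#' @param search_ms Pre-peak window searched for the kink.
#' @export
spike_kink <- function(waveform, dt_ms, frac = 0.033, search_ms = 5) {
  if (length(waveform) < 2) stop_invalid("waveform needs >= 2 samples")
  pk <- which.max(waveform)
  d <- diff(waveform) / dt_ms
  md <- max(d[seq_len(max(pk - 1L, 1L))])
  if (md <= 0) stop_invalid("waveform has no rising phase")
  lo <- max(1L, pk - round(search_ms / dt_ms))
  hi <- lo - 1L + which.max(d[lo:(pk - 1L)])  # fastest-rise sample
  rng <- lo:hi
  below <- rng[d[rng] < frac * md]
  idx <- if (length(below)) below[length(below)] + 1L else rng[1]
  waveform[min(idx, pk)]
}

#' Full width at half height of a spike waveform
#'
#' Half height is measured from the kink voltage (the spike's take-off)
#' to the peak; crossing times are linearly interpolated between the
#' bracketing samples.
#'
#' @inheritParams spike_kink
#' @return Width in ms.
#' @export
spike_fwhm <- function(waveform, dt_ms, frac = 0.033) {
  pk <- which.max(waveform)
  v_half <- (spike_kink(waveform, dt_ms, frac) + waveform[pk]) / 2
  cross_t <- function(i, j) {
    # linear interpolation of the half-height crossing between i and j
    i + (v_half - waveform[i]) / (waveform[j] - waveform[i])
  }
  below_pre <- which(waveform[seq_len(pk - 1L)] < v_half)
  if (!length(below_pre))
    stop_invalid("waveform does not cross half height on the rise")
  i_up <- below_pre[length(below_pre)]
  post <- which(waveform[(pk + 1L):length(waveform)] < v_half)
  if (!length(post))
    stop_invalid("waveform does not cross half height on the fall")
  i_dn <- pk + post[1] - 1L
  (cross_t(i_dn, i_dn + 1L) - cross_t(i_up, i_up + 1L)) * dt_ms
}

#' Shape metrics of a cell's mean spike waveform
#'
#' Convenience wrapper: extracts waveforms, averages, and measures the
#' kink, max dV/dt and width at half height on the mean waveform.
#'
#' @inheritParams extract_spike_waveforms
#' @param per_spike If `TRUE`, also return a per-spike metric table.
#' @return List with `kink_mV`, `max_dvdt`, `fwhm_ms`, `n_spikes`, and
#'   optionally `per_spike`.
#' @export
spike_shape_metrics <- function(vm, spikes, pre_ms = 5, post_ms = 10,
                                isolated_ms = 5, per_spike = FALSE) {
  wf <- extract_spike_waveforms(vm, spikes, pre_ms, post_ms, isolated_ms)
  if (nrow(wf$waveforms) == 0)
    return(list(kink_mV = NA_real_, max_dvdt = NA_real_,
                fwhm_ms = NA_real_, n_spikes = 0L))
  out <- list(kink_mV = spike_kink(wf$mean, wf$dt_ms),
              max_dvdt = max_dvdt(wf$mean, wf$dt_ms),
              fwhm_ms = spike_fwhm(wf$mean, wf$dt_ms),
              n_spikes = nrow(wf$waveforms))
  if (per_spike)
    out$per_spike <- data.frame(
      kink_mV = apply(wf$waveforms, 1, spike_kink, dt_ms = wf$dt_ms),
      max_dvdt = apply(wf$waveforms, 1, max_dvdt, dt_ms = wf$dt_ms),
      fwhm_ms = apply(wf$waveforms, 1, spike_fwhm, dt_ms = wf$dt_ms))
  out
}

#' Slope of the firing rate vs injected current (F-I) curve
#'
#' Ordinary least-squares slope of rate against current over the
#' suprathreshold range (currents at or above the smallest current that
#' evoked spikes).  Returns 0 when no current evoked any spikes.
#'
#' @param currents_pA Injected current amplitudes, pA.
#' @param rates_hz Evoked firing rates, Hz.
#' @return Slope in Hz/pA.
#' @export
fi_slope <- function(currents_pA, rates_hz) {
  if (length(currents_pA) != length(rates_hz))
    stop_invalid("currents and rates must have equal length")
  if (length(currents_pA) < 3)
    stop_invalid("need >= 3 current levels")
  if (all(rates_hz == 0)) return(0)
  thr <- min(currents_pA[rates_hz > 0])
  keep <- currents_pA >= thr
  if (sum(keep) < 2) keep <- rep(TRUE, length(currents_pA))
  unname(stats::coef(stats::lm(rates_hz[keep] ~ currents_pA[keep]))[2])
}
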