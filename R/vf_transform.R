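# Voltage-to-firing-rate transform: 30 ms paired binning of spike-
# filtered Vm and firing rate, rectified power-law fitting with the
# exponent constrained to [1, 4], and the 1 mV empirical curve.

new_vf_transform <- function(b, vth, alpha, rmse = NA_real_,
                             degenerate = FALSE, n_pairs = NA_integer_) {
  structure(list(b = b, vth = vth, alpha = alpha, rmse = rmse,
                 degenerate = degenerate, n_pairs = n_pairs),
            class = "vf_transform")
}

#' @export
print.vf_transform <- function(x, ...) {
  cat(sprintf(
    "<vf_transform> FR(V) = %.3g * max(V - %.2f, 0)^%.2f  (RMSE %.2f%s)\n",
    x$b, x$vth, x$alpha, x$rmse,
    if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

#' Paired Vm / firing-rate observations in 30 ms bins
#'
#' Averages the spike-filtered Vm and counts spikes in non-overlapping
#' `bin_ms` windows; a partial trailing bin is dropped.
#'
#' @param vm_filtered A `vm_trace` (spike-filtered, smoothed, and
#'   baseline-handled per the preprocessing chain).
#' @param spikes A `spike_train`.
#' @param bin_ms Bin width, ms (default 30).
#' @return A `vm_rate_pairs`: `vm_mV`, `rate_hz`, `bin_ms`.
#' @export
bin_vm_rate <- function(vm_filtered, spikes, bin_ms = 30) {
  vm <- vm_filtered
  stopifnot(inherits(vm, "vm_trace"), inherits(spikes, "spike_train"))
  per <- round(bin_ms / vm$dt_ms)
  n_bins <- floor(length(vm$samples) / per)
  if (n_bins < 1) stop_invalid("trace shorter than one bin")
  v <- vm$samples[seq_len(n_bins * per)]
  vm_mean <- colMeans(matrix(v, nrow = per))
  tm <- spikes$times_ms - vm$t0_ms
  tm <- tm[tm >= 0 & tm < n_bins * bin_ms]
  counts <- tabulate(floor(tm / bin_ms) + 1L, nbins = n_bins)
  structure(list(vm_mV = vm_mean, rate_hz = counts / (bin_ms / 1000),
                 bin_ms = bin_ms), class = "vm_rate_pairs")
}

# 1 mV binning of pairs: centers, mean rate, SEM, count.
bin_pairs_1mv <- function(pairs, bin_mV = 1) {
  edges <- floor(min(pairs$vm_mV) / bin_mV) * bin_mV
  idx <- floor((pairs$vm_mV - edges) / bin_mV) + 1L
  n_bins <- max(idx)
  count <- tabulate(idx, nbins = n_bins)
  sums <- tapply(pairs$rate_hz, factor(idx, levels = seq_len(n_bins)), sum)
  sums[is.na(sums)] <- 0
  mean_rate <- ifelse(count > 0, as.numeric(sums) / count, NA_real_)
  sem <- vapply(seq_len(n_bins), function(i) {
    if (count[i] > 1) stats::sd(pairs$rate_hz[idx == i]) / sqrt(count[i])
    else NA_real_
  }, numeric(1))
  vsums <- tapply(pairs$vm_mV, factor(idx, levels = seq_len(n_bins)), sum)
  vsums[is.na(vsums)] <- 0
  list(centers = edges + (seq_len(n_bins) - 0.5) * bin_mV,
       mean_vm = ifelse(count > 0, as.numeric(vsums) / count, NA_real_),
       mean_rate = mean_rate, sem_rate = sem, count = count)
}

#' Fit a rectified power law to Vm / rate pairs
#'
#' `FR(V) = b * max(V - Vth, 0)^alpha`, with `alpha` constrained to
#' \[1, 4\].  By default the objective is weighted least squares on
#' 1 mV-binned mean rates with the bin counts as weights; set
#' `weight_by_count = FALSE` to fit the raw 30 ms pairs.  `Vth` is
#' multi-started on a 1 mV grid spanning the observed voltages (ties go
#' to the lowest `Vth`), with a final continuous polish.
#'
#' @param pairs A `vm_rate_pairs` from [bin_vm_rate()].
#' @param weight_by_count Weighted binned-mean objective (default) or
#'   raw-pair objective.
#' @return A `vf_transform`; when every rate is zero a degenerate fit
#'   (`b = 0`, `Vth = max(Vm)`) is flagged.
#' @export
fit_power_law <- function(pairs, weight_by_count = TRUE) {
  stopifnot(inherits(pairs, "vm_rate_pairs"))
  if (length(pairs$vm_mV) < 30)
    warning("fewer than 30 Vm/rate pairs; fit may be unreliable")
  if (all(pairs$rate_hz == 0))
    return(new_vf_transform(0, max(pairs$vm_mV), 1, rmse = 0,
                            degenerate = TRUE,
                            n_pairs = length(pairs$vm_mV)))
  if (weight_by_count) {
    bb <- bin_pairs_1mv(pairs)
    ok <- bb$count > 0
    v <- bb$mean_vm[ok]; r <- bb$mean_rate[ok]; w <- bb$count[ok]
  } else {
    v <- pairs$vm_mV; r <- pairs$rate_hz; w <- rep(1, length(v))
  }
  fit_given_vth <- function(vth) {
    u <- pmax(v - vth, 0)
    if (all(u == 0)) return(list(b = 0, alpha = 1, sse = sum(w * r^2)))
    obj <- function(alpha) {
      ua <- u^alpha
      b <- max(sum(w * r * ua) / sum(w * ua^2), 0)
      sum(w * (r - b * ua)^2)
    }
    op <- stats::optimize(obj, c(1, 4))
    ua <- u^op$minimum
    list(b = max(sum(w * r * ua) / sum(w * ua^2), 0),
         alpha = op$minimum, sse = op$objective)
  }
  grid <- seq(floor(min(v)), ceiling(max(v)), by = 1)
  best <- NULL; best_vth <- NA
  for (vth in grid) {
    f <- fit_given_vth(vth)
    if (is.null(best) || f$sse < best$sse - 1e-12) {
      best <- f; best_vth <- vth
    }
  }
  # continuous polish of (log-b, vth, alpha) from the grid optimum
  par0 <- c(log(max(best$b, 1e-6)), best_vth, best$alpha)
  objf <- function(p) {
    u <- pmax(v - p[2], 0)
    sum(w * (r - exp(p[1]) * u^p[3])^2)
  }
  pol <- try(stats::optim(par0, objf, method = "L-BFGS-B",
                          lower = c(-20, min(v) - 5, 1),
                          upper = c(20, max(v), 4)), silent = TRUE)
  if (!inherits(pol, "try-error") && pol$value < best$sse) {
    best <- list(b = exp(pol$par[1]), alpha = pol$par[3], sse = pol$value)
    best_vth <- pol$par[2]
  }
  new_vf_transform(best$b, best_vth, best$alpha,
                   rmse = sqrt(best$sse / sum(w)),
                   n_pairs = length(pairs$vm_mV))
}

#' Empirical voltage-to-firing-rate curve in 1 mV bins
#'
#' Mean and SEM firing rate per 1 mV voltage bin, reported from the
#' lowest populated bin up to (exclusive) the first bin that does not
#' contain at least `min_count` pairs.
#'
#' @param pairs A `vm_rate_pairs`.
#' @param bin_mV Voltage bin width, mV.
#' @param min_count Minimum pairs per reported bin (default 15).
#' @return List with `bin_centers_mV`, `mean_rate`, `sem_rate`, `count`,
#'   `truncation_mV` (first excluded bin center, `NA` if none).
#' @export
empirical_curve <- function(pairs, bin_mV = 1, min_count = 15) {
  stopifnot(inherits(pairs, "vm_rate_pairs"))
  bb <- bin_pairs_1mv(pairs, bin_mV)
  first <- which(bb$count > 0)[1]
  stop_at <- first
  while (stop_at <= length(bb$count) && bb$count[stop_at] >= min_count)
    stop_at <- stop_at + 1L
  keep <- seq_len(stop_at - 1L)
  keep <- keep[keep >= first]
  list(bin_centers_mV = bb$centers[keep],
       mean_rate = bb$mean_rate[keep],
       sem_rate = bb$sem_rate[keep],
       count = bb$count[keep],
       truncation_mV = if (stop_at <= length(bb$count))
         bb$centers[stop_at] else NA_real_)
}

#' Predicted firing rate per bin from a fitted transform
#'
#' Applies `FR(V) = b * max(V - Vth, 0)^alpha` to the bin-mean Vm of
#' the trace, using the same binning as the fit.
#'
#' @param transform A `vf_transform`.
#' @param vm_filtered A `vm_trace` preprocessed like the fitting data.
#' @param bin_ms Bin width, ms.
#' @return Numeric vector of predicted rates (Hz), one per bin.
#' @export
predict_rate <- function(transform, vm_filtered, bin_ms = 30) {
  stopifnot(inherits(transform, "vf_transform"))
  vm <- vm_filtered
  v <- if (inherits(vm, "vm_trace")) {
    per <- round(bin_ms / vm$dt_ms)
    n_bins <- floor(length(vm$samples) / per)
    colMeans(matrix(vm$samples[seq_len(n_bins * per)], nrow = per))
  } else as.numeric(vm)
  vf_rate(transform, v)
}
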