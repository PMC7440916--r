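# STRF estimation by reverse correlation of spike-filtered Vm with the
# sparse-noise stimulus, ON/OFF subunit extraction by thresholded
# connected components, ellipse-moment shape analysis, and spectral
# (2-D FFT) prediction of direction selectivity.

new_strf_map <- function(corr, lag_axis_ms, space_axis_deg, normalized) {
  structure(list(corr = corr, lag_axis_ms = lag_axis_ms,
                 space_axis_deg = space_axis_deg, normalized = normalized),
            class = "strf_map")
}

#' @export
print.strf_map <- function(x, ...) {
  cat(sprintf("<strf_map> %d positions x %d lag bins (0-%g ms)%s\n",
              nrow(x$corr), ncol(x$corr), max(x$lag_axis_ms),
              if (x$normalized) ", correlation coefficients" else ""))
  invisible(x)
}

#' Reverse correlation of Vm with a sparse-noise stimulus
#'
#' For every bar position independently, the contrast sequence is
#' cross-correlated with the (spike-filtered) Vm trace at lags from 0 to
#' `max_lag_ms`, then averaged into `lag_bin_ms` pixels.  The raw
#' correlation is reported without whitening, so the map is blurred in
#' time by the 100 ms stimulus frame; with `normalize = TRUE` (default)
#' values are Pearson correlation coefficients, otherwise covariances.
#'
#' @param vm_filtered A `vm_trace` with spikes removed.
#' @param stimulus A `stimulus_movie` (sparse noise).
#' @param max_lag_ms Largest lag analysed, ms.
#' @param lag_bin_ms STRF pixel size along the lag axis, ms.
#' @param normalize Report correlation coefficients (`TRUE`) or raw
#'   covariances.
#' @return A `strf_map` (positions x lag bins).
#' @export
reverse_correlate <- function(vm_filtered, stimulus, max_lag_ms = 400,
                              lag_bin_ms = 10, normalize = TRUE) {
  vm <- vm_filtered
  stopifnot(inherits(vm, "vm_trace"), inherits(stimulus, "stimulus_movie"))
  dt <- vm$dt_ms
  s <- upsample_stimulus(stimulus, dt)
  n <- min(length(vm$samples), ncol(s))
  v <- vm$samples[seq_len(n)] - mean(vm$samples[seq_len(n)])
  s <- s[, seq_len(n), drop = FALSE]
  n_lag <- round(max_lag_ms / dt)
  m <- stats::nextn(n + n_lag, 2)
  vf <- stats::fft(c(v, numeric(m - n)))
  sd_v <- sqrt(mean(v^2))
  cc <- matrix(0, nrow(s), n_lag)
  warned <- FALSE
  for (i in seq_len(nrow(s))) {
    si <- s[i, ] - mean(s[i, ])
    sd_s <- sqrt(mean(si^2))
    if (sd_s == 0 || sd_v == 0) {
      if (normalize && !warned) {
        warning("zero-variance stimulus position; column(s) set to 0")
        warned <- TRUE
      }
      next
    }
    sf <- stats::fft(c(si, numeric(m - n)))
    # cross-correlation r_sv(l) = sum_t s(t) v(t + l), lags l = 0..n_lag-1
    r <- Re(stats::fft(Conj(sf) * vf, inverse = TRUE))[seq_len(n_lag)] / m
    cov <- r / n
    cc[i, ] <- if (normalize) cov / (sd_s * sd_v) else cov
  }
  # average into lag-bin pixels
  fac <- round(lag_bin_ms / dt)
  n_bins <- floor(n_lag / fac)
  idx <- rep(seq_len(n_bins), each = fac)
  binned <- t(apply(cc[, seq_len(n_bins * fac), drop = FALSE], 1,
                    function(row) tapply(row, idx, mean)))
  if (nrow(s) == 1) binned <- matrix(binned, nrow = 1)
  new_strf_map(binned, (seq_len(n_bins) - 0.5) * lag_bin_ms,
               stimulus$space_axis_deg, normalize)
}

# 4- or 8-connected components of a logical mask, via igraph.
label_components <- function(mask, connectivity = 8) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 0) return(list())
  key <- function(r, c) (c - 1) * nrow(mask) + r
  ids <- key(px[, 1], px[, 2])
  lookup <- seq_len(nrow(px))
  names(lookup) <- as.character(ids)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else if (connectivity != 4)
    stop_invalid("`connectivity` must be 4 or 8")
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    r2 <- px[, 1] + offs[k, 1]
    c2 <- px[, 2] + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nrow(mask) & c2 >= 1 & c2 <= ncol(mask)
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (!any(ok)) next
    edges <- rbind(edges, cbind(which(ok),
                                unname(lookup[as.character(key(r2[ok], c2[ok]))])))
  }
  g <- igraph::graph_from_edgelist(
    rbind(cbind(seq_len(nrow(px)), seq_len(nrow(px))), edges),
    directed = FALSE)
  comp <- igraph::components(g)$membership[seq_len(nrow(px))]
  lapply(split(seq_len(nrow(px)), comp), function(j)
    px[j, , drop = FALSE])
}

#' Extract ON and OFF subunits from an STRF
#'
#' Thresholds the map at the brightest and darkest `pixel_fraction`
#' tails (computed over the whole image per tail), labels connected
#' components, and discards clusters smaller than `min_pixels` as
#' spurious.
#'
#' @param strf A `strf_map`.
#' @param pixel_fraction Tail fraction per polarity (default 0.05).
#' @param min_pixels Minimum accepted cluster size (default 20).
#' @param connectivity Pixel connectivity, 4 or 8.
#' @return List of clusters; each has `polarity` (`"ON"`/`"OFF"`),
#'   `pixels` (matrix of position-, lag-indices) and `values`.
#' @export
extract_subunits <- function(strf, pixel_fraction = 0.05, min_pixels = 20,
                             connectivity = 8) {
  stopifnot(inherits(strf, "strf_map"))
  img <- strf$corr
  if (length(img) == 0 || all(img == 0)) return(list())
  thr_on <- stats::quantile(img, 1 - pixel_fraction, type = 7)
  thr_off <- stats::quantile(img, pixel_fraction, type = 7)
  out <- list()
  for (pol in c("ON", "OFF")) {
    mask <- if (pol == "ON") img >= thr_on & img > 0
            else img <= thr_off & img < 0
    comps <- label_components(mask, connectivity)
    for (cl in comps) {
      if (nrow(cl) < min_pixels) next
      out[[length(out) + 1L]] <- list(
        polarity = pol, pixels = cl,
        values = img[cl])
    }
  }
  out
}

#' Ellipse with the same second moments as a pixel cluster
#'
#' Region-moment ellipse: normalized second central moments of the pixel
#' set (with the 1/12 per-pixel variance of a unit square added) define
#' an ellipse whose axes are the eigenvectors of the moment matrix.
#' Eccentricity is `sqrt(1 - (minor/major)^2)` and the orientation is
#' the acute angle between the major axis and the space axis.
#'
#' @param cluster A cluster from [extract_subunits()] (or a bare
#'   two-column pixel index matrix: position index, lag index).
#' @return A `subunit_shape` with `polarity`, `pixel_count`, `centroid`
#'   (position, lag, px), `major_axis_px`, `minor_axis_px`,
#'   `eccentricity`, `orientation_deg` (acute, degrees),
#'   `orientation_signed_deg`, `area_px` (ellipse area).
#' @export
fit_ellipse <- function(cluster) {
  px <- if (is.list(cluster) && !is.null(cluster$pixels)) cluster$pixels
        else cluster
  if (nrow(px) < 1) stop_invalid("empty cluster")
  x <- px[, 1]   # position (space) pixel index
  t <- px[, 2]   # lag (time) pixel index
  n <- length(x)
  mxx <- sum((x - mean(x))^2) / n + 1 / 12
  mtt <- sum((t - mean(t))^2) / n + 1 / 12
  mxt <- sum((x - mean(x)) * (t - mean(t))) / n
  common <- sqrt((mxx - mtt)^2 + 4 * mxt^2)
  major <- 2 * sqrt(2) * sqrt(mxx + mtt + common)
  minor <- 2 * sqrt(2) * sqrt(max(mxx + mtt - common, 1 / 12))
  phi <- 0.5 * atan2(2 * mxt, mxx - mtt)   # major axis vs space axis
  structure(list(
    polarity = if (is.list(cluster)) cluster$polarity %||% NA_character_
               else NA_character_,
    pixel_count = n,
    centroid_px = c(position = mean(x), lag = mean(t)),
    major_axis_px = major,
    minor_axis_px = minor,
    eccentricity = sqrt(1 - (minor / major)^2),
    orientation_deg = abs(phi) * 180 / pi,
    orientation_signed_deg = phi * 180 / pi,
    area_px = pi * (major / 2) * (minor / 2)
  ), class = "subunit_shape")
}

#' Physical extents and latencies of a subunit ellipse
#'
#' Converts the moment ellipse to physical units via the STRF axes: the
#' spatial and temporal extents are the widths of the ellipse's tangent
#' projections onto the space and lag axes, and the minimum / maximum
#' latencies are the ellipse's lower / upper tangent bounds on the lag
#' axis (the minimum may be negative because the raw correlation is
#' blurred by the stimulus frame).
#'
#' @param shape A `subunit_shape` from [fit_ellipse()].
#' @param space_axis_deg,lag_axis_ms The STRF pixel axes.
#' @return The shape with `spatial_extent_deg`, `temporal_extent_ms`,
#'   `min_latency_ms`, `max_latency_ms` added.
#' @export
shape_parameters <- function(shape, space_axis_deg, lag_axis_ms) {
  stopifnot(inherits(shape, "subunit_shape"))
  dx <- mean(diff(space_axis_deg))
  dl <- mean(diff(lag_axis_ms))
  a <- shape$major_axis_px / 2
  b <- shape$minor_axis_px / 2
  phi <- shape$orientation_signed_deg * pi / 180
  ext_x <- 2 * sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
  ext_t <- 2 * sqrt((a * sin(phi))^2 + (b * cos(phi))^2)
  ct_ms <- lag_axis_ms[1] + (shape$centroid_px["lag"] - 1) * dl
  shape$spatial_extent_deg <- ext_x * dx
  shape$temporal_extent_ms <- ext_t * dl
  shape$min_latency_ms <- unname(ct_ms - ext_t / 2 * dl)
  shape$max_latency_ms <- unname(ct_ms + ext_t / 2 * dl)
  shape
}

# The nine reported shape parameters of one subunit, as a named vector.
shape_parameter_names <- c("eccentricity", "major_axis_px",
                           "minor_axis_px", "orientation_deg", "area_px",
                           "spatial_extent_deg", "temporal_extent_ms",
                           "min_latency_ms", "max_latency_ms")

#' Subunit shape analysis of an STRF
#'
#' Runs [extract_subunits()], [fit_ellipse()] and [shape_parameters()]
#' and returns one row per accepted subunit.
#'
#' @inheritParams extract_subunits
#' @return Data frame with `polarity`, `pixel_count`, `peak_corr` (the
#'   subunit's extreme map value) and the nine shape parameters.
#' @export
subunit_shapes <- function(strf, pixel_fraction = 0.05, min_pixels = 20,
                           connectivity = 8) {
  clusters <- extract_subunits(strf, pixel_fraction, min_pixels,
                               connectivity)
  rows <- lapply(clusters, function(cl) {
    sh <- shape_parameters(fit_ellipse(cl), strf$space_axis_deg,
                           strf$lag_axis_ms)
    data.frame(polarity = cl$polarity,
               pixel_count = sh$pixel_count,
               peak_corr = cl$values[which.max(abs(cl$values))],
               as.list(unlist(sh[shape_parameter_names])))
  })
  if (!length(rows))
    return(data.frame())
  do.call(rbind, rows)
}

#' Cell-average subunit shape parameters
#'
#' Unweighted mean of each of the nine shape parameters across all of a
#' cell's accepted ON and OFF subunits.
#'
#' @param subunits Data frame from [subunit_shapes()].
#' @return Named numeric vector (or `NULL` when there are no subunits).
#' @export
cell_average <- function(subunits) {
  if (is.null(subunits) || nrow(subunits) == 0) return(NULL)
  colMeans(subunits[, shape_parameter_names, drop = FALSE])
}

#' Peak-correlation control across polarity x group classes
#'
#' One-way ANOVA of absolute subunit peak correlations across the four
#' classes (naive/experienced x ON/OFF); an insignificant result
#' indicates that map SNR differences do not drive group differences in
#' shape parameters.
#'
#' @param peaks_by_class Named list of >= 2 numeric vectors of absolute
#'   peak correlations, one per class.
#' @return The ANOVA p-value.
#' @export
peak_correlation_check <- function(peaks_by_class) {
  if (any(lengths(peaks_by_class) < 2))
    stop_invalid("need >= 2 values per class")
  responsiveness_anova(peaks_by_class)
}

#' Predicted direction selectivity from the STRF amplitude spectrum
#'
#' The 2-D DFT amplitudes of the STRF are summed over the two quadrants
#' with spatial frequency in `(0, sf_max]` and temporal frequency in
#' `(0, tf_max]` or `[-tf_max, 0)` (DC row and column excluded); the
#' larger sum is the predicted preferred response and
#' `dsi_pr = (R_pref - R_null) / R_pref`.  A separable STRF has a
#' tf-sign-symmetric amplitude spectrum and hence `dsi_pr = 0`.
#'
#' @param strf A `strf_map` (also accepts a `kernel_strf`).
#' @param sf_max Spatial frequency limit, cycles/degree.
#' @param tf_max Temporal frequency limit, Hz.
#' @return List with `R_pref`, `R_null`, `dsi_pr`.
#' @export
predict_dsi_fft <- function(strf, sf_max = 0.2, tf_max = 10) {
  if (inherits(strf, "kernel_strf"))
    strf <- new_strf_map(strf$weights, strf$lag_axis_ms,
                         strf$space_axis_deg, FALSE)
  stopifnot(inherits(strf, "strf_map"))
  img <- strf$corr
  if (all(img == 0)) stop_invalid("all-zero map: predicted DSI undefined")
  dx <- mean(diff(strf$space_axis_deg))
  dl_s <- mean(diff(strf$lag_axis_ms)) / 1000
  amp <- Mod(stats::fft(img))
  fx <- fft_freqs(nrow(img), dx)          # cycles/degree
  ft <- fft_freqs(ncol(img), dl_s)        # Hz
  sel_x <- fx > 0 & fx <= sf_max
  q1 <- sum(amp[sel_x, ft > 0 & ft <= tf_max, drop = FALSE])
  q2 <- sum(amp[sel_x, ft < 0 & ft >= -tf_max, drop = FALSE])
  R_pref <- max(q1, q2)
  R_null <- min(q1, q2)
  list(R_pref = R_pref, R_null = R_null,
       dsi_pr = (R_pref - R_null) / R_pref)
}
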