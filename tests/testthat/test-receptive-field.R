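# Reverse correlation, subunit extraction, ellipse geometry, spectral
# DSI prediction.

test_that("reverse correlation behaves as a matched filter", {
  # delta kernel: argmax of the STRF at the kernel's (position, lag)
  k <- make_ground_truth_kernel(5, 40, amplitude = 0,
                                space_axis = seq(-7.75, 7.75, by = 3.1),
                                lag_axis = 0:300)
  k$weights[3, 151] <- 1  # position 3, lag 150 ms
  stim <- make_sparse_noise(6, duration_s = 120, seed = 5)
  vm <- simulate_vm(stim, k, noise_sd = 0.5, dt_ms = 1, seed = 6)
  strf <- reverse_correlate(vm, stim, max_lag_ms = 300)
  peak <- which(abs(strf$corr) == max(abs(strf$corr)), arr.ind = TRUE)
  expect_equal(unname(peak[1, 1]), 3)
  expect_lt(abs(strf$lag_axis_ms[peak[1, 2]] - 150), 110)
  # constant Vm gives an all-zero map (with a zero-variance warning)
  expect_warning(flat <- reverse_correlate(flat_vm(-70, 12000), stim),
                 "zero-variance")
  expect_true(all(flat$corr == 0))
  # DC invariance of the normalized map
  vm2 <- vm; vm2$samples <- vm$samples + 13.7
  strf2 <- reverse_correlate(vm2, stim, max_lag_ms = 300)
  expect_equal(strf2$corr, strf$corr, tolerance = 1e-9)
})

test_that("estimated STRF matches the frame-blurred kernel", {
  cell <- test_cell("experienced", seed = 7)
  rec <- simulate_cell_noise(cell, duration_s = 150, seed = 21,
                             inject = FALSE)
  strf <- reverse_correlate(remove_spikes_median(rec$vm), rec$stimulus)
  oracle <- blur_kernel(cell$kernel, shape = "triangle")
  expect_gt(cor(as.vector(strf$corr), as.vector(oracle$corr)), 0.9)
  # estimator consistency: correlation non-decreasing with duration
  cc <- vapply(c(30, 150), function(dur) {
    r <- simulate_cell_noise(cell, duration_s = dur, seed = 21)
    s <- reverse_correlate(remove_spikes_median(r$vm), r$stimulus)
    cor(as.vector(s$corr), as.vector(oracle$corr))
  }, numeric(1))
  expect_true(diff(cc) > -0.02)
})

test_that("subunit extraction enforces the size and polarity rules", {
  img <- matrix(0, 20, 40)
  img[3:5, 5:7] <- 0.9        # 9-pixel ON blob: rejected
  base <- strfdev:::new_strf_map(img, (1:40) * 10 - 5,
                                 seq(-29.45, 29.45, length.out = 20),
                                 TRUE)
  expect_length(extract_subunits(base, min_pixels = 20), 0)
  img2 <- matrix(rnorm(800, sd = 1e-3), 20, 40)
  img2[3:8, 5:9] <- 0.9       # 30-pixel ON
  img2[12:17, 20:24] <- -0.9  # 30-pixel OFF
  m2 <- strfdev:::new_strf_map(img2, (1:40) * 10 - 5,
                               seq(-29.45, 29.45, length.out = 20), TRUE)
  subs <- extract_subunits(m2, min_pixels = 20)
  expect_length(subs, 2)
  expect_setequal(vapply(subs, `[[`, "", "polarity"), c("ON", "OFF"))
  expect_true(all(vapply(subs, function(s) nrow(s$pixels), 1L) == 30))
  expect_length(extract_subunits(strfdev:::new_strf_map(
    matrix(0, 4, 4), 1:4, 1:4, TRUE)), 0)
})

test_that("connected-component labelling agrees with EBImage (4-conn)", {
  skip_if_not_installed("EBImage")
  set.seed(12)
  for (i in 1:5) {
    mask <- matrix(runif(400) < 0.3, 20, 20)
    ours <- strfdev:::label_components(mask, connectivity = 4)
    ref <- EBImage::bwlabel(matrix(as.numeric(mask), 20, 20))
    expect_equal(length(ours), max(ref))
    sizes_ours <- unname(sort(vapply(ours, nrow, 1L)))
    sizes_ref <- sort(as.integer(table(ref[ref > 0])))
    expect_equal(sizes_ours, sizes_ref)
  }
  # diagonal pixels merge under 8- but not 4-connectivity
  d <- matrix(FALSE, 4, 4); d[1, 1] <- d[2, 2] <- TRUE
  expect_length(strfdev:::label_components(d, 4), 2)
  expect_length(strfdev:::label_components(d, 8), 1)
})

test_that("moment ellipses reproduce known geometry", {
  disc <- fit_ellipse(filled_disc(30, 30, 10))
  expect_lt(disc$eccentricity, 0.1)
  expect_lt(abs(disc$major_axis_px / disc$minor_axis_px - 1), 0.05)
  rect <- fit_ellipse(filled_rect(1:10, 1:40))  # 10 rows x 40 cols
  # major axis along the lag (col) axis -> orientation 90 degrees
  expect_equal(rect$orientation_deg, 90, tolerance = 1)
  expect_equal(rect$major_axis_px / rect$minor_axis_px, 4,
               tolerance = 0.2)
  rect2 <- fit_ellipse(filled_rect(1:40, 1:10))
  expect_equal(rect2$orientation_deg, 0, tolerance = 1)
})

test_that("rotation moves orientation and preserves eccentricity/area", {
  px <- filled_rect(1:30, 1:8)
  base <- fit_ellipse(px)
  th <- 30 * pi / 180
  ctr <- colMeans(px)
  rot <- cbind(cos(th) * (px[, 1] - ctr[1]) - sin(th) * (px[, 2] - ctr[2]),
               sin(th) * (px[, 1] - ctr[1]) + cos(th) * (px[, 2] - ctr[2]))
  rshape <- fit_ellipse(rot)
  expect_equal(abs(rshape$orientation_signed_deg -
                     base$orientation_signed_deg), 30, tolerance = 3)
  expect_equal(rshape$eccentricity, base$eccentricity, tolerance = 0.02)
  expect_equal(rshape$area_px, base$area_px, tolerance = 0.05 * base$area_px)
})

test_that("ellipse moments agree with EBImage region features", {
  skip_if_not_installed("EBImage")
  px <- filled_disc(20, 25, 8, 50, 50)
  img <- matrix(0, 50, 50); img[px] <- 1
  ours <- fit_ellipse(px)
  suppressWarnings({
    ft <- EBImage::computeFeatures.moment(img)
  })
  expect_equal(ours$major_axis_px, unname(ft[1, "m.majoraxis"]),
               tolerance = 0.05 * ours$major_axis_px)
  expect_equal(ours$eccentricity, unname(ft[1, "m.eccentricity"]),
               tolerance = 0.05)
})

test_that("physical extents and latencies match the ellipse tangents", {
  # axis-aligned ellipse: centre lag 150 ms, semi-axes 20 deg x 50 ms
  sh <- structure(list(polarity = "ON", pixel_count = 100,
                       centroid_px = c(position = 8, lag = 15.5),
                       major_axis_px = 2 * 50 / 10,   # lag px are 10 ms
                       minor_axis_px = 2 * 20 / 3.1,
                       eccentricity = 0.5,
                       orientation_deg = 90,
                       orientation_signed_deg = 90,
                       area_px = 1), class = "subunit_shape")
  space_axis <- (1:16 - 8.5) * 3.1
  lag_axis <- (1:40) * 10 - 5
  out <- shape_parameters(sh, space_axis, lag_axis)
  expect_equal(out$min_latency_ms, 100, tolerance = 1e-6)
  expect_equal(out$max_latency_ms, 200, tolerance = 1e-6)
  expect_equal(out$temporal_extent_ms, 100, tolerance = 1e-6)
  expect_equal(out$spatial_extent_deg, 40, tolerance = 1e-6)
  # rotating the ellipse by 90 degrees swaps the extents (in px units)
  sh90 <- sh; sh90$orientation_signed_deg <- 0
  out90 <- shape_parameters(sh90, space_axis, lag_axis)
  expect_equal(out90$temporal_extent_ms / 10,
               out$spatial_extent_deg / 3.1, tolerance = 1e-6)
})

test_that("tilted-ellipse extents match a dense boundary-sampling oracle", {
  set.seed(31)
  for (i in 1:20) {
    a <- runif(1, 4, 15); b <- runif(1, 1, a)
    phi <- runif(1, -90, 90)
    ctr <- c(position = runif(1, 5, 12), lag = runif(1, 10, 30))
    sh <- structure(list(polarity = "ON", pixel_count = 50,
                         centroid_px = ctr, major_axis_px = 2 * a,
                         minor_axis_px = 2 * b,
                         eccentricity = sqrt(1 - (b / a)^2),
                         orientation_deg = abs(phi),
                         orientation_signed_deg = phi,
                         area_px = pi * a * b),
                    class = "subunit_shape")
    out <- shape_parameters(sh, (1:16) * 3.1, (1:40) * 10 - 5)
    th <- seq(0, 2 * pi, length.out = 1e5)
    phr <- phi * pi / 180
    xs <- a * cos(th) * cos(phr) - b * sin(th) * sin(phr)
    ts <- a * cos(th) * sin(phr) + b * sin(th) * cos(phr)
    expect_lt(abs(out$spatial_extent_deg / 3.1 - diff(range(xs))), 1)
    expect_lt(abs(out$temporal_extent_ms / 10 - diff(range(ts))), 1)
    lag_ctr <- (ctr["lag"] - 1) * 10 + 5
    expect_lt(abs(out$min_latency_ms - (lag_ctr + min(ts) * 10)), 10)
  }
})

test_that("cell averages pool subunits; peak-correlation control works", {
  one <- data.frame(polarity = "ON", pixel_count = 30, peak_corr = 0.5,
                    eccentricity = 0.9, major_axis_px = 10,
                    minor_axis_px = 3, orientation_deg = 70,
                    area_px = 24, spatial_extent_deg = 12,
                    temporal_extent_ms = 90, min_latency_ms = 50,
                    max_latency_ms = 140)
  expect_equal(unname(cell_average(one)["min_latency_ms"]), 50)
  two <- rbind(one, one)
  two$min_latency_ms <- c(50, 150)
  expect_equal(unname(cell_average(two)["min_latency_ms"]), 100)
  expect_null(cell_average(data.frame()))
  set.seed(13)
  peaks <- list(Naive_ON = rnorm(10, 0.5, 0.05),
                Naive_OFF = rnorm(10, 0.5, 0.05),
                Exp_ON = rnorm(10, 0.5, 0.05),
                Exp_OFF = rnorm(10, 0.5, 0.05))
  expect_gt(peak_correlation_check(peaks), 0.05)
  peaks$Exp_ON <- peaks$Exp_ON + 0.5
  expect_lt(peak_correlation_check(peaks), 0.001)
})

test_that("spectral DSI prediction: separability, drift, polarity", {
  sep <- make_ground_truth_kernel(5, 40, tilt = 0, t_center = 120)
  expect_equal(predict_dsi_fft(sep)$dsi_pr, 0, tolerance = 1e-9)
  drift <- make_ground_truth_kernel(20, 150, tilt = 0.004,
                                    t_center = 200,
                                    lag_axis = 0:400)
  expect_gt(predict_dsi_fft(drift)$dsi_pr, 0.8)
  expect_error(predict_dsi_fft(strfdev:::new_strf_map(
    matrix(0, 8, 8), 1:8, 1:8, TRUE)), "zero")
  # negating the kernel swaps ON/OFF subunits with identical geometry
  cell <- test_cell("experienced", seed = 3)
  strf <- blur_kernel(cell$kernel)
  neg <- strf; neg$corr <- -neg$corr
  s1 <- subunit_shapes(strf)
  s2 <- subunit_shapes(neg)
  expect_equal(nrow(s1), nrow(s2))
  o1 <- s1[order(s1$min_latency_ms, s1$eccentricity), ]
  o2 <- s2[order(s2$min_latency_ms, s2$eccentricity), ]
  expect_equal(o1$eccentricity, o2$eccentricity, tolerance = 1e-9)
  expect_true(all(o1$polarity != o2$polarity))
  expect_equal(predict_dsi_fft(neg)$dsi_pr, predict_dsi_fft(strf)$dsi_pr,
               tolerance = 1e-9)
})
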