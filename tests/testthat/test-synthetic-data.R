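# Stimulus, kernel and forward-simulation generators.

test_that("grating stimuli are bounded cosines with the stated geometry", {
  g <- make_grating_stimulus(0, tf_hz = 4, duration_s = 1)
  expect_true(all(g$contrast >= -1 & g$contrast <= 1))
  # opposite directions differ only in the temporal sign
  g0 <- make_grating_stimulus(0, tf_hz = 4, duration_s = 1, frame_ms = 10)
  g180 <- make_grating_stimulus(180, tf_hz = 4, duration_s = 1,
                                frame_ms = 10)
  x <- g0$space_axis_deg
  t_s <- (seq_len(ncol(g0$contrast)) - 1) * 0.01
  expect_equal(g180$contrast,
               cos(2 * pi * outer(0.08 * x, 4 * t_s, "+")),
               tolerance = 1e-12)
  # sf = 0.08 cpd has a 12.5 degree period: rows 4 bars apart repeat
  # when bars are 3.125 degrees wide
  gp <- make_grating_stimulus(0, duration_s = 0.5, bar_width_deg = 3.125)
  expect_equal(gp$contrast[1, ], gp$contrast[5, ], tolerance = 1e-9)
})

test_that("grating argument validation", {
  expect_error(make_grating_stimulus(0, duration_s = -1), "duration")
  expect_error(make_grating_stimulus(0, n_positions = 0), "n_positions")
})

test_that("sparse noise has the stated frame count, determinism, rates", {
  sn <- make_sparse_noise(4, duration_s = 10, frame_ms = 100, seed = 1)
  expect_equal(ncol(sn$contrast), 100)
  expect_true(all(sn$contrast %in% c(-1, 0, 1)))
  sn2 <- make_sparse_noise(4, duration_s = 10, frame_ms = 100, seed = 1)
  expect_identical(sn$contrast, sn2$contrast)
  big <- make_sparse_noise(1, duration_s = 1e4, frame_ms = 100, seed = 7)
  freqs <- table(factor(big$contrast, levels = c(-1, 0, 1))) / 1e5
  expect_true(all(abs(freqs - c(0.1, 0.8, 0.1)) < 0.01))
  expect_error(make_sparse_noise(4, p_black = 0.7, p_white = 0.5),
               "<= 1")
})

test_that("ground-truth kernels: separability, zero amplitude, tilt", {
  k0 <- make_ground_truth_kernel(5, 40, tilt = 0, t_center = 120)
  expect_equal(predict_dsi_fft(k0)$dsi_pr, 0, tolerance = 1e-9)
  kz <- make_ground_truth_kernel(5, 40, tilt = 0.001, amplitude = 0)
  expect_true(all(kz$weights == 0))
  expect_error(make_ground_truth_kernel(5, 40, lag_axis = -10:100),
               "negative")
  # predicted DSI strictly increases with |tilt|
  dsis <- vapply(c(0.0001, 0.0004, 0.0008, 0.0014, 0.0022),
                 function(tl) predict_dsi_fft(
                   make_ground_truth_kernel(5, 50, tilt = tl,
                                            t_center = 110))$dsi_pr,
                 numeric(1))
  expect_true(all(diff(dsis) > 0))
})

test_that("simulate_vm is the exact discrete convolution of the LN model", {
  # delta kernel reproduces the (shifted) stimulus
  lagax <- 0:50
  spax <- c(-3.1, 0, 3.1)
  k <- make_ground_truth_kernel(5, 40, amplitude = 0, space_axis = spax,
                                lag_axis = lagax)
  k$weights[2, 21] <- 1   # position x0 = 0, lag 20 ms
  stim <- make_sparse_noise(3, duration_s = 2, frame_ms = 10, seed = 3)
  vm <- simulate_vm(stim, k, noise_sd = 0, baseline_mV = -70, dt_ms = 1)
  up <- strfdev:::upsample_stimulus(stim, 1)
  n <- length(vm$samples)
  expect_equal(vm$samples[30:n], -70 + up[2, 30:n - 20],
               tolerance = 1e-9)

  # independent triple-loop oracle on a small random kernel
  set.seed(11)
  k$weights <- matrix(rnorm(3 * 51, sd = 0.2), 3, 51)
  vm2 <- simulate_vm(stim, k, noise_sd = 0, dt_ms = 1)
  direct <- rep(-70, 200)
  for (ti in 1:200) for (xi in 1:3) for (li in 0:50)
    if (ti - li >= 1)
      direct[ti] <- direct[ti] + k$weights[xi, li + 1] * up[xi, ti - li]
  expect_equal(vm2$samples[1:200], direct, tolerance = 1e-9)

  # linearity: doubled contrast doubles the deflection
  stim2 <- stim; stim2$contrast <- 2 * stim$contrast
  vm3 <- simulate_vm(stim2, k, noise_sd = 0, dt_ms = 1)
  expect_equal(vm3$samples + 70, 2 * (vm2$samples + 70),
               tolerance = 1e-9)

  # zero kernel, zero noise: constant baseline
  k$weights[] <- 0
  vm4 <- simulate_vm(stim, k, noise_sd = 0, dt_ms = 1)
  expect_true(all(vm4$samples == -70))
})

test_that("simulate_spikes: rectification, refractoriness, rate calibration", {
  vm <- flat_vm(-70, 2000)
  vf <- list(b = 1, vth = -60, alpha = 2)
  expect_length(simulate_spikes(vm, vf, seed = 1)$times_ms, 0)
  # constant 20 Hz for 100 s: count within 3 sigma of 2000
  vm2 <- flat_vm(-60 + sqrt(20), 1e5)
  sp <- simulate_spikes(vm2, vf, refractory_ms = 0, seed = 2)
  expect_lt(abs(length(sp$times_ms) - 2000), 3 * sqrt(2000))
  # ISIs respect the refractory period
  vm3 <- flat_vm(-50, 2e4)
  sp3 <- simulate_spikes(vm3, vf, refractory_ms = 5, seed = 3)
  expect_true(all(diff(sp3$times_ms) >= 5))
})

test_that("spike injection sums templates and leaves empty trains alone", {
  vm <- flat_vm(-65, 5000, dt_ms = 0.1)
  expect_identical(inject_spike_waveforms(vm, spikes_at(numeric(0)),
                                          list(kink_mV = -25,
                                               max_dvdt_mV_per_ms = 160,
                                               fwhm_ms = 1.5))$samples,
                   vm$samples)
  shape <- list(kink_mV = -28, max_dvdt_mV_per_ms = 200, fwhm_ms = 1.2,
                amplitude_mV = 65)
  inj <- inject_spike_waveforms(vm, spikes_at(c(100, 150)), shape)
  # two spikes 50 ms apart on a flat trace: windows are identical
  w1 <- inj$samples[995:1105]
  w2 <- inj$samples[1495:1605]
  expect_equal(w1, w2, tolerance = 1e-9)
  expect_error(inject_spike_waveforms(vm, spikes_at(1e6), shape),
               "outside")
})

test_that("populations are deterministic and match configured presets", {
  expect_length(make_cell_population("naive", 0, seed = 1), 0)
  p1 <- make_cell_population("experienced", 3, seed = 9)
  p2 <- make_cell_population("experienced", 3, seed = 9)
  expect_identical(population_table(p1), population_table(p2))
  expect_error(make_cell_population("adolescent"), "arg")
  # preset fidelity at n = 200: mean spike-shape parameters
  pt <- population_table(make_cell_population("experienced", 200,
                                              seed = 42))
  expect_lt(abs(mean(pt$kink_mV) - (-30.2)), 1)
  expect_lt(abs(mean(pt$max_dvdt) - 264.4) / 264.4, 0.05)
  expect_lt(abs(mean(pt$fwhm_ms) - 1.0), 0.15)
})
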