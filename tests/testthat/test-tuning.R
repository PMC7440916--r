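# F0/F1 analysis, classification, tuning fits, DSI, latency.

test_that("cycle_fourier recovers analytic sinusoids exactly", {
  dt <- 1
  t_s <- (0:3999) * dt / 1000
  r <- 3 + 5 * cos(2 * pi * 4 * t_s)
  cf <- cycle_fourier(r, 4, dt)
  expect_equal(cf$F0, 3, tolerance = 1e-9)
  expect_equal(cf$F1, 5, tolerance = 1e-9)
  cf0 <- cycle_fourier(rep(2.5, 1000), 4, dt)
  expect_equal(cf0$F0, 2.5)
  expect_equal(cf0$F1, 0, tolerance = 1e-9)
  # an 8 Hz harmonic does not leak into F1 at 4 Hz
  r2 <- 1 + 2 * cos(2 * pi * 4 * t_s) + 7 * cos(2 * pi * 8 * t_s)
  expect_equal(cycle_fourier(r2, 4, dt)$F1, 2, tolerance = 1e-9)
  expect_error(cycle_fourier(r[1:100], 4, dt), "cycle")
})

test_that("simple/complex classification follows the stated boundaries", {
  expect_equal(classify_simple_complex(1.0, NA, TRUE), "simple")
  expect_equal(classify_simple_complex(0.99, NA, TRUE), "complex")
  expect_equal(classify_simple_complex(NA, 0.6, FALSE), "simple")
  expect_equal(classify_simple_complex(NA, 0.5, FALSE), "complex")
  expect_error(classify_simple_complex(NaN, NA, TRUE), "undefined")
})

test_that("double-Gaussian fit recovers generating parameters", {
  dirs <- seq(0, 337.5, by = 22.5)
  flat <- fit_double_gaussian(dirs, rep(4, length(dirs)))
  expect_lt(flat$Rp, 0.2)
  expect_lt(abs(flat$R0 + flat$Rp / 2 - 4), 1)
  set.seed(7)
  truth <- function(th) 1 +
    10 * exp(-strfdev:::angle_diff(th, 90)^2 / (2 * 25^2)) +
    4 * exp(-strfdev:::angle_diff(th, 270)^2 / (2 * 25^2))
  fit <- fit_double_gaussian(dirs, truth(dirs) + rnorm(16, 0, 0.1))
  expect_lt(abs(fit$Rp - 10) / 10, 0.1)
  expect_lt(abs(fit$Rn - 4) / 4, 0.1)
  expect_lt(strfdev:::angle_diff(fit$theta_p, 90), 5)
  expect_lt(abs(fit$sigma - 25) / 25, 0.1)
  expect_error(fit_double_gaussian(c(0, 90, 180, 270), rep(1, 4)),
               "6 distinct")
})

test_that("wrapped angular distance", {
  expect_equal(strfdev:::angle_diff(350, 10), 20)
  expect_equal(strfdev:::angle_diff(0, 180), 180)
  expect_equal(strfdev:::angle_diff(90, 90), 0)
})

test_that("dsi definition, bounds and scale invariance", {
  expect_equal(dsi(10, 10), 0)
  expect_equal(dsi(10, 0), 1)
  # printed experienced spiking group means: (24.7 - 9.0) / 24.7
  expect_equal(dsi(24.7, 9.0), 0.6356275, tolerance = 1e-6)
  expect_equal(dsi(10, -3), 1)       # negative null rectified
  expect_true(is.na(dsi(0, 1)))
  for (c_scale in c(0.5, 2, 17))
    expect_equal(dsi(c_scale * 8, c_scale * 3), dsi(8, 3))
})

test_that("dsi_from_curve uses the fit only to locate the peak", {
  dirs <- seq(0, 315, by = 45)
  resp <- c(2, 4, 12, 4, 2, 1, 3, 1)  # peak at 90, opposite 270
  out <- dsi_from_curve(dirs, resp)
  expect_equal(out$theta_p, 90)
  expect_equal(out$Rp, 12)
  expect_equal(out$Rn, 3)
  expect_equal(out$dsi, (12 - 3) / 12)
})

test_that("responsiveness ANOVA gates unresponsive cells", {
  same <- replicate(8, rep(5, 4), simplify = FALSE)
  expect_equal(responsiveness_anova(same), 1)
  set.seed(3)
  resp <- replicate(8, rnorm(4), simplify = FALSE)
  resp[[3]] <- resp[[3]] + 10
  expect_lt(responsiveness_anova(resp), 0.001)
  # agrees with the classical F test
  y <- lapply(1:4, function(i) rnorm(5, i * 0.3))
  p_pkg <- responsiveness_anova(y)
  df <- data.frame(y = unlist(y), g = factor(rep(1:4, each = 5)))
  p_ref <- stats::oneway.test(y ~ g, df, var.equal = TRUE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  expect_error(responsiveness_anova(list(1:3)), "2 stimuli")
})

test_that("response latency finds the k-sigma crossing", {
  x <- rep(0, 500); x[81:500] <- 10
  vm <- strfdev:::new_vm_trace(x, 1)
  expect_equal(response_latency(vm, 0, 1, k = 6), 80, tolerance = 1)
  set.seed(8)
  noise <- strfdev:::new_vm_trace(rnorm(2000), 1)
  expect_true(is.na(response_latency(noise, 0, 1, k = 6)))
  expect_error(response_latency(vm, 0, 0), "SD")
})

test_that("latency tracks the kernel's temporal center", {
  base <- list(sigma_x = 5, sigma_t = 30, tilt = 5e-4, amplitude = 8)
  lat <- vapply(c(90, 110), function(tc) {
    k <- make_ground_truth_kernel(base$sigma_x, base$sigma_t,
                                  tilt = base$tilt, t_center = tc)
    g <- strfdev:::kernel_grating_gain(k, 4)
    k$weights <- k$weights * (10 / g$gain)
    stim <- make_grating_stimulus(if (g$pref_s == 1) 0 else 180,
                                  duration_s = 2, frame_ms = 1)
    vm <- simulate_vm(stim, k, noise_sd = 0, dt_ms = 1)
    response_latency(vm, -70, 0.05, k = 6)
  }, numeric(1))
  expect_equal(lat[2] - lat[1], 20, tolerance = 6)
})

test_that("expansive spiking sharpens DSI relative to Vm", {
  # power law with alpha > 1: spike DSI >= Vm DSI per cell
  for (seed in 1:4) {
    cell <- make_cell_population(if (seed %% 2) "naive" else
      "experienced", 1, seed = seed)[[1]]
    gr <- simulate_cell_gratings(cell, n_trials = 2, duration_s = 4,
                                 seed = 100 + seed)
    f1 <- function(tr) cycle_fourier(tr$vm$samples - cell$baseline_mV,
                                     4, 1)$F1
    rate <- function(tr) length(tr$spikes$times_ms) / 4
    vm_dsi <- dsi(mean(vapply(gr$pref, f1, numeric(1))),
                  mean(vapply(gr$null, f1, numeric(1))))
    sp_p <- mean(vapply(gr$pref, rate, numeric(1)))
    sp_n <- mean(vapply(gr$null, rate, numeric(1)))
    if (sp_p > 0)
      expect_gte(dsi(sp_p, sp_n), vm_dsi - 0.05)
  }
})
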