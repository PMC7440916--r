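# End-to-end synthetic experiment: generate naive and experienced
# populations, simulate recordings, and run every analysis stage,
# returning the tables and group statistics as one report.

#' Default pipeline configuration
#'
#' @param seed Master seed; every stage derives its stream from it.
#' @param n_cells Cells per group.
#' @param grating_trials,grating_duration_s Grating protocol.
#' @param noise_duration_s Sparse-noise duration per cell, s.
#' @param mixture_n_sim,mixture_n_cells Bootstrap settings.
#' @return A configuration list for [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1, n_cells = 8, grating_trials = 4,
                            grating_duration_s = 4,
                            noise_duration_s = 120,
                            mixture_n_sim = 2000, mixture_n_cells = 20) {
  list(seed = seed, n_cells = n_cells, grating_trials = grating_trials,
       grating_duration_s = grating_duration_s,
       noise_duration_s = noise_duration_s,
       mixture_n_sim = mixture_n_sim, mixture_n_cells = mixture_n_cells,
       tf_hz = 4, dt_ms = 1, spike_dt_ms = 0.1)
}

# Grating-response tuning metrics of one simulated cell.
analyze_cell_tuning <- function(gratings, baseline, tf_hz, dt_ms) {
  per_dir <- lapply(gratings, function(trials) {
    vm_f0 <- vm_f1 <- sp_f0 <- sp_f1 <- numeric(0)
    for (tr in trials) {
      filt <- remove_spikes_median(tr$vm)
      cf <- cycle_fourier(filt$samples - baseline, tf_hz, dt_ms)
      vm_f0 <- c(vm_f0, cf$F0); vm_f1 <- c(vm_f1, cf$F1)
      rt <- rate_from_spikes(tr$spikes, tr$vm$t0_ms,
                             length(tr$vm$samples) * dt_ms, bin_ms = dt_ms)
      cs <- cycle_fourier(rt$rate_hz, tf_hz, dt_ms)
      sp_f0 <- c(sp_f0, cs$F0); sp_f1 <- c(sp_f1, cs$F1)
    }
    list(vm_f0 = mean(vm_f0), vm_f1 = mean(vm_f1),
         sp_f0 = mean(sp_f0), sp_f1 = mean(sp_f1),
         n_spikes = sum(vapply(trials, function(tr)
           length(tr$spikes$times_ms), numeric(1))))
  })
  p <- per_dir$pref; n <- per_dir$null
  has_spikes <- (p$n_spikes + n$n_spikes) >= 10
  list(
    vm_dsi_f0 = dsi(max(p$vm_f0, 0), n$vm_f0),
    vm_dsi_f1 = dsi(p$vm_f1, n$vm_f1),
    vm_dsi_total = dsi(max(p$vm_f0, 0) + p$vm_f1,
                       max(n$vm_f0, 0) + n$vm_f1),
    spike_dsi_f0 = dsi(p$sp_f0, n$sp_f0),
    spike_dsi_f1 = dsi(p$sp_f1, n$sp_f1),
    spike_dsi_total = dsi(p$sp_f0 + p$sp_f1, n$sp_f0 + n$sp_f1),
    vm_pref_total = max(p$vm_f0, 0) + p$vm_f1,
    vm_null_total = max(n$vm_f0, 0) + n$vm_f1,
    spike_pref_total = p$sp_f0 + p$sp_f1,
    spike_null_total = n$sp_f0 + n$sp_f1,
    vm_mod_ratio = if (p$vm_f0 > 0) p$vm_f1 / p$vm_f0 else Inf,
    spike_mod_ratio = if (p$sp_f0 > 0) p$sp_f1 / p$sp_f0 else NA_real_,
    has_spikes = has_spikes,
    class = if (has_spikes && p$sp_f0 > 0)
      classify_simple_complex(p$sp_f1 / p$sp_f0, NA, TRUE)
    else classify_simple_complex(NA, if (p$vm_f0 > 0)
      p$vm_f1 / p$vm_f0 else Inf, FALSE))
}

#' Run the full synthetic experiment
#'
#' Generates both populations, simulates grating and sparse-noise
#' recordings for every cell, and runs preprocessing, tuning analysis,
#' STRF estimation with subunit shape analysis and spectral DSI
#' prediction, spike-shape metrics (at 0.1 ms sampling), V-F transform
#' fitting, the four-condition bootstrap mixture model, and the group
#' statistics.
#'
#' @param config List from [pipeline_config()].
#' @param out_dir Optional directory; when given, per-cell tables are
#'   written as CSV and the summary as JSON.
#' @return A report list: `cells` (per-cell data frame), `subunits`,
#'   `mixture` (per-condition `bootstrap_result`s), `comparisons`
#'   (group tests), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cfg <- utils::modifyList(pipeline_config(), config)
  groups <- c("naive", "experienced")
  pops <- list(
    naive = make_cell_population("naive", cfg$n_cells, seed = cfg$seed),
    experienced = make_cell_population("experienced", cfg$n_cells,
                                       seed = cfg$seed + 1000))
  cells <- list(); subunits <- list()
  waves <- list(naive = list(), experienced = list())
  transforms <- list(naive = list(), experienced = list())
  for (g in groups) {
    for (i in seq_along(pops[[g]])) {
      cell <- pops[[g]][[i]]
      cseed <- cfg$seed + 7919 * i + 13 * (g == "experienced")
      gr <- simulate_cell_gratings(cell, n_trials = cfg$grating_trials,
                                   duration_s = cfg$grating_duration_s,
                                   dt_ms = cfg$dt_ms, tf_hz = cfg$tf_hz,
                                   seed = cseed, inject = TRUE)
      baseline <- cell$baseline_mV
      tun <- analyze_cell_tuning(gr, baseline, cfg$tf_hz, cfg$dt_ms)
      noise <- simulate_cell_noise(cell,
                                   duration_s = cfg$noise_duration_s,
                                   dt_ms = cfg$dt_ms, seed = cseed + 1,
                                   inject = TRUE)
      filt <- remove_spikes_median(noise$vm)
      strf <- reverse_correlate(filt, noise$stimulus)
      shp <- subunit_shapes(strf)
      ca <- cell_average(shp)
      pr <- try(predict_dsi_fft(strf), silent = TRUE)
      # spike shape at fine sampling
      fine <- simulate_cell_gratings(cell, n_trials = 1, duration_s = 4,
                                     dt_ms = cfg$spike_dt_ms,
                                     tf_hz = cfg$tf_hz, seed = cseed + 2,
                                     inject = TRUE)
      shape <- spike_shape_metrics(fine$pref[[1]]$vm,
                                   fine$pref[[1]]$spikes)
      vf <- fit_power_law(bin_vm_rate(filt, noise$spikes))
      wv <- cell_waveforms(
        lapply(gr, function(trials) lapply(trials, function(tr)
          remove_spikes_median(tr$vm))),
        dt_ms = cfg$dt_ms, pref = 1L)
      waves[[g]] <- c(waves[[g]], list(wv))
      transforms[[g]] <- c(transforms[[g]], list(vf))
      row <- data.frame(
        id = cell$id, group = g, class = tun$class,
        has_spikes = tun$has_spikes,
        vm_dsi_total = tun$vm_dsi_total,
        spike_dsi_total = tun$spike_dsi_total,
        vm_dsi_f0 = tun$vm_dsi_f0, vm_dsi_f1 = tun$vm_dsi_f1,
        spike_dsi_f0 = tun$spike_dsi_f0,
        spike_dsi_f1 = tun$spike_dsi_f1,
        vm_pref = tun$vm_pref_total, vm_null = tun$vm_null_total,
        spike_pref = tun$spike_pref_total,
        spike_null = tun$spike_null_total,
        dsi_pr = if (inherits(pr, "try-error")) NA_real_ else pr$dsi_pr,
        n_subunits = nrow(shp),
        kink_mV = shape$kink_mV, max_dvdt = shape$max_dvdt,
        fwhm_ms = shape$fwhm_ms,
        vf_b = vf$b, vf_vth = vf$vth, vf_alpha = vf$alpha)
      if (!is.null(ca))
        row <- cbind(row, as.data.frame(as.list(ca)))
      cells[[length(cells) + 1L]] <- row
      if (nrow(shp))
        subunits[[length(subunits) + 1L]] <-
          cbind(data.frame(id = cell$id, group = g), shp)
    }
  }
  cells <- do.call(rbind, lapply(cells, function(r) {
    miss <- setdiff(shape_parameter_names, names(r))
    for (m in miss) r[[m]] <- NA_real_
    r
  }))
  subunits <- if (length(subunits)) do.call(rbind, subunits) else
    data.frame()
  mixture <- list()
  for (wg in groups) for (tg in groups)
    mixture[[paste(wg, tg, sep = "_")]] <-
      bootstrap_mixture(waves[[wg]], transforms[[tg]],
                        n_sim = cfg$mixture_n_sim,
                        n_cells = cfg$mixture_n_cells,
                        seed = cfg$seed + 42)
  nv <- cells$group == "naive"
  cmp <- list(
    vm_dsi = compare_groups(cells$vm_dsi_total[nv],
                            cells$vm_dsi_total[!nv], "wrs",
                            parameter = "vm_dsi_total"),
    spike_dsi = compare_groups(cells$spike_dsi_total[nv],
                               cells$spike_dsi_total[!nv], "wrs",
                               parameter = "spike_dsi_total"),
    eccentricity = compare_groups(cells$eccentricity[nv],
                                  cells$eccentricity[!nv], "wrs",
                                  n_family = 9,
                                  parameter = "eccentricity"),
    min_latency = compare_groups(cells$min_latency_ms[nv],
                                 cells$min_latency_ms[!nv], "wrs",
                                 n_family = 9,
                                 parameter = "min_latency_ms"),
    max_dvdt = compare_groups(cells$max_dvdt[nv], cells$max_dvdt[!nv],
                              "wrs", n_family = 3,
                              parameter = "max_dvdt"),
    spiking_fraction = compare_groups(
      c(sum(cells$has_spikes[nv]), sum(!cells$has_spikes[nv])),
      c(sum(cells$has_spikes[!nv]), sum(!cells$has_spikes[!nv])),
      "fisher", parameter = "spiking_fraction"))
  report <- list(cells = cells, subunits = subunits, mixture = mixture,
                 comparisons = cmp, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(subunits, file.path(out_dir, "subunits.csv"),
                     row.names = FALSE)
    summ <- list(
      config = cfg[c("seed", "n_cells", "noise_duration_s")],
      group_means = lapply(split(cells$vm_dsi_total, cells$group), mean),
      mixture = lapply(mixture, function(m) list(
        mean_dsi = mean(m$sim_mean_dsi),
        mean_rate = mean(m$sim_mean_rate),
        pct5 = m$pct5, pct95 = m$pct95)),
      comparisons = lapply(cmp, function(x)
        list(parameter = x$parameter, p_raw = x$p_raw,
             p_bonferroni = x$p_bonferroni)))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}
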