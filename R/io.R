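# Plain-text serialization of recordings: a directory with CSV matrices
# and a JSON metadata file.  An equivalent of an array container that
# stays human-readable and diff-able.

#' Write a recording to a plain-text container
#'
#' Creates `dir/` with `vm.csv` (`t_ms`, `vm_mV`), `spikes.csv`
#' (`t_ms`), `stimulus.csv` (positions x frames contrast matrix) and
#' `meta.json` (sampling, stimulus axes, cell metadata).
#'
#' @param recording List with `vm` (`vm_trace`), `spikes`
#'   (`spike_train`), `stimulus` (`stimulus_movie`), and optional
#'   `meta` (named list).
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vm <- recording$vm
  utils::write.csv(data.frame(t_ms = vm_times_ms(vm),
                              vm_mV = vm$samples),
                   file.path(dir, "vm.csv"), row.names = FALSE)
  utils::write.csv(data.frame(t_ms = recording$spikes$times_ms),
                   file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.table(recording$stimulus$contrast,
                     file.path(dir, "stimulus.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  st <- recording$stimulus
  meta <- c(list(dt_ms = vm$dt_ms, t0_ms = vm$t0_ms,
                 frame_ms = st$frame_ms,
                 bar_width_deg = st$bar_width_deg, kind = st$kind,
                 direction_deg = st$direction_deg, tf_hz = st$tf_hz,
                 sf_cpd = st$sf_cpd),
            recording$meta %||% list())
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Directory containing the container files.
#' @return List with `vm`, `spikes`, `stimulus`, `meta`.
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  vm_df <- utils::read.csv(file.path(dir, "vm.csv"))
  sp_df <- utils::read.csv(file.path(dir, "spikes.csv"))
  contrast <- as.matrix(utils::read.table(file.path(dir, "stimulus.csv"),
                                          sep = ","))
  dimnames(contrast) <- NULL
  storage.mode(contrast) <- "double"
  stim <- new_stimulus_movie(contrast, meta$frame_ms, meta$bar_width_deg,
                             meta$kind,
                             direction_deg = meta$direction_deg %||% NA,
                             tf_hz = meta$tf_hz %||% NA,
                             sf_cpd = meta$sf_cpd %||% NA)
  list(vm = new_vm_trace(vm_df$vm_mV, meta$dt_ms, meta$t0_ms %||% 0),
       spikes = new_spike_train(sp_df$t_ms),
       stimulus = stim, meta = meta)
}
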