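# Shared fixtures built in code.

flat_vm <- function(mV = -70, n = 1000, dt_ms = 1) {
  strfdev:::new_vm_trace(rep(mV, n), dt_ms)
}

spikes_at <- function(times_ms) strfdev:::new_spike_train(times_ms)

# A mid-sized experienced-like cell used across tests (deterministic).
test_cell <- function(group = "experienced", seed = 21) {
  make_cell_population(group, 1, seed = seed)[[1]]
}

# Bare vm_rate_pairs constructor for fitting tests.
mk_pairs <- function(vm, rate, bin_ms = 30) {
  structure(list(vm_mV = vm, rate_hz = rate, bin_ms = bin_ms),
            class = "vm_rate_pairs")
}

# Pixel-cluster fixture: filled shapes on an r x c grid.
filled_disc <- function(r0, c0, radius, nr = 60, nc = 60) {
  px <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  px <- px[(px$row - r0)^2 + (px$col - c0)^2 <= radius^2, ]
  as.matrix(px)
}

filled_rect <- function(rows, cols) {
  as.matrix(expand.grid(row = rows, col = cols))
}

with_seed_rnorm <- function(seed, n, sd) {
  set.seed(seed)
  rnorm(n, 0, sd)
}
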