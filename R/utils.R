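# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# The caller's RNG state is restored afterwards, so generators are pure
# functions of their arguments.  `seed = NULL` uses the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop_invalid(sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0)
    stop_invalid(sprintf("`%s` must be > 0", name))
  invisible(x)
}

# Odd sample count >= 3 for a window given in ms.
odd_samples <- function(window_ms, dt_ms) {
  k <- max(3L, round(window_ms / dt_ms))
  if (k %% 2 == 0) k <- k + 1L
  as.integer(k)
}

# Causal convolution y[t] = sum_{tau>=0} k[tau+1] * x[t-tau] via FFT.
conv_causal <- function(x, k) {
  n <- length(x)
  m <- stats::nextn(n + length(k) - 1L, 2)
  xf <- stats::fft(c(x, numeric(m - n)))
  kf <- stats::fft(c(k, numeric(m - length(k))))
  Re(stats::fft(xf * kf, inverse = TRUE))[seq_len(n)] / m
}

# Signed DFT frequencies for n samples at spacing d (cycles per unit of d).
fft_freqs <- function(n, d) {
  idx <- 0:(n - 1)
  idx[idx > n / 2] <- idx[idx > n / 2] - n
  idx / (n * d)
}
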