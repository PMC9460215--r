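# Independent oracles used across the suite.

# Direct O(N^2) discrete Fourier transform magnitude, written from the
# definition; independent of the FFT-based implementation path.
naive_dft_mag <- function(x) {
  n <- length(x)
  j <- seq_len(n) - 1
  vapply(j, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * j / n)))
  }, numeric(1))
}

# The normalization fft_transform applies, restated from its contract.
log_minmax <- function(mag) {
  v <- log1p(mag)
  if (max(v) == min(v)) return(rep(-1, length(v)))
  2 * (v - min(v)) / (max(v) - min(v)) - 1
}

# Brute-force count of valid kernel placements: positions i = 0, s, 2s, ...
# whose window of length k fits inside the padded input.
count_placements <- function(L, k, s, p) {
  i <- 0L; n <- 0L
  while (i + k <= L + 2 * p) {
    n <- n + 1L
    i <- i + s
  }
  n
}

# Small, fast synthetic conditions shared by training-free tests.
quick_cfg <- function(duration_s = 5) {
  synth_config(duration_s = duration_s)
}
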