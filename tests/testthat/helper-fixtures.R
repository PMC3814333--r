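# Small shared fixtures built in code.

# A tiny oscillator sheet with fixed phases/frequencies.
tiny_sheet <- function(n = 8, seed = 1, freq_sd = 4) {
  oscillator_sheet(n, freq_mean_hz = 20, freq_sd_hz = freq_sd, seed = seed)
}

# Periodic (minimum-image) index helper for brute-force convolutions.
wrap_idx <- function(i, n) ((i - 1) %% n) + 1

# Brute-force pairwise Kuramoto coupling term for every oscillator.
brute_coupling <- function(phases, kernel) {
  n <- nrow(phases)
  w <- kernel$weights
  half <- (kernel$extent - 1) / 2
  out <- matrix(0, n, n)
  for (r in 1:n) for (c in 1:n) {
    acc <- 0
    for (dr in -half:half) for (dc in -half:half) {
      acc <- acc + w[dr + half + 1, dc + half + 1] *
        sin(phases[wrap_idx(r + dr, n), wrap_idx(c + dc, n)] - phases[r, c])
    }
    out[r, c] <- acc
  }
  out
}

# Oscillation amplitude of a trace via half the peak-to-peak excursion.
amp_pp <- function(x) (max(x) - min(x)) / 2
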