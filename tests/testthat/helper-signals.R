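# small signal builders shared across tests

make_sinusoid <- function(f, fs = 200, n = 1600, amp = 1, phase = 0) {
  eeg_signal(amp * sin(2 * pi * f * (seq_len(n) - 1) / fs + phase), fs = fs)
}

make_noise <- function(n = 1600, fs = 200, sd = 1, seed = 1) {
  withr::with_seed(seed, eeg_signal(stats::rnorm(n, 0, sd), fs = fs))
}

# explicit O(K*L) diagonal average of d * u v^T, the oracle for the
# convolution-based fast path used inside ssa()
oracle_rank1_diag <- function(d, u, v) {
  diagonal_average(d * outer(u, v))
}

rel_l2 <- function(a, b) {
  sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
}
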