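# Shared fixtures, built in code.

# seeded random well-conditioned 2x2 FIR plant
random_plant <- function(seed = 42, len = 64, M = 2, L = 2, fs = 48000) {
  set.seed(seed)
  ir_set(array(stats::rnorm(len * M * L), c(len, M, L)), fs)
}

# diagonal plant: pure per-path delays with identity coupling
diagonal_delay_plant <- function(delays = c(10, 17), len = 64, fs = 48000) {
  irs <- array(0, c(len, 2, 2))
  irs[delays[1] + 1, 1, 1] <- 1
  irs[delays[2] + 1, 2, 2] <- 1
  ir_set(irs, fs)
}

# a trivial filter bank realizing given per-path FIR kernels (for metric
# unit tests that do not need the design pipeline)
manual_bank <- function(filters, fs = 48000, total_delay = 0L,
                        fft_size = 512) {
  structure(
    list(
      filters = filters, sample_rate = fs,
      n_spks = dim(filters)[2], n_mics = dim(filters)[3],
      total_delay = as.integer(total_delay), causal_shift = 0L,
      level_comp = 1,
      lowpass = NULL,
      config = design_config(fft_size = fft_size, lowpass_taps = 0),
      window = NULL
    ),
    class = "inverse_filter_bank"
  )
}

# identity 2x2 plant (unit impulses on the diagonal paths)
identity_plant <- function(len = 8, fs = 48000) {
  irs <- array(0, c(len, 2, 2))
  irs[1, 1, 1] <- 1
  irs[1, 2, 2] <- 1
  ir_set(irs, fs)
}

# short sweep spec used across sweep tests
short_sweep <- function() {
  sweep_spec(f_start = 10, f_end = 24000, duration = 2,
             pre_silence = 0.1, post_silence = 0.1)
}

expect_max_abs <- function(x, tol) {
  expect_lt(max(abs(x)), tol)
}
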