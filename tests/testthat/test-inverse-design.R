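test_that("global normalization preserves relative path levels", {
  set.seed(2)
  irs <- ir_set(array(rnorm(32 * 2 * 2) * 0.25, c(32, 2, 2)))
  n1 <- normalize_set(irs)
  expect_equal(max(abs(n1$irs)), 1)
  scale <- n1$irs[1, 1, 1] / irs$irs[1, 1, 1]
  expect_max_abs(n1$irs - irs$irs * scale, 1e-12)
  expect_max_abs(normalize_set(n1)$irs - n1$irs, 1e-12)  # idempotent
  expect_error(normalize_set(ir_set(array(0, c(8, 1, 1)))), "all-zero")
})

test_that("the modified Tukey window passes, tapers and zeroes as specified", {
  spec <- tukey_window_spec(10, 16, 64, 24)
  w <- ctcva:::build_window(spec, 256)
  expect_equal(w[seq_len(10)], rep(0, 10))
  expect_equal(w[10 + 16 + seq_len(64)], rep(1, 64))        # flat passes
  expect_equal(w[(10 + 16 + 64 + 24 + 1):256], rep(0, 256 - 114))
  expect_true(all(w >= 0 & w <= 1))

  # zero-length fades degenerate to a rectangular window
  rect <- ctcva:::build_window(tukey_window_spec(5, 0, 40, 0), 128)
  expect_equal(sum(rect), 40)

  expect_error(ctcva:::build_window(tukey_window_spec(0, 0, 300, 0), 128),
               "exceeds")
  irs <- random_plant(seed = 1, len = 64)
  win <- apply_window(irs, tukey_window_spec(0, 4, 20, 8))
  expect_max_abs(win$irs[33:64, , ], 1e-15)
})

test_that("per-bin Tikhonov inverse matches its closed forms", {
  I2 <- diag(2) + 0i
  expect_max_abs(Mod(tikhonov_bin_inverse(I2, 0) - I2), 1e-12)
  beta <- 0.37
  expect_max_abs(Mod(tikhonov_bin_inverse(I2, beta) - I2 / (1 + beta)), 1e-12)
  G <- matrix(c(1, 0.5, 0.5, 1), 2, 2) + 0i
  H_expected <- matrix(c(4 / 3, -2 / 3, -2 / 3, 4 / 3), 2, 2)
  expect_max_abs(Mod(tikhonov_bin_inverse(G, 0) - H_expected), 1e-12)

  sing <- matrix(1 + 0i, 2, 2)
  expect_error(tikhonov_bin_inverse(sing, 0, freq = 440), "440")
  expect_error(tikhonov_bin_inverse(I2, -1), "non-negative")
})

test_that("regularized inverse agrees with a brute-force dense solve", {
  set.seed(12)
  for (dims in list(c(2, 2), c(2, 3))) {
    M <- dims[1]; L <- dims[2]
    for (beta in c(0, 1e-4, 1e-2)) {
      G <- matrix(complex(real = rnorm(M * L), imaginary = rnorm(M * L)), M, L)
      H <- tikhonov_bin_inverse(G, beta)
      A <- G %*% Conj(t(G)) + beta * diag(M)
      oracle <- Conj(t(G)) %*% solve(A, diag(M) + 0i)
      expect_max_abs(Mod(H - oracle), 1e-10)
    }
  }
})

test_that("loudspeaker effort is non-increasing in the regularization", {
  set.seed(13)
  for (rep in 1:5) {
    G <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2, 2)
    norms <- vapply(c(0, 1e-4, 1e-3, 1e-2), function(b) {
      sqrt(sum(Mod(tikhonov_bin_inverse(G, b))^2))
    }, numeric(1))
    expect_true(all(diff(norms) <= 1e-12))
  }
})

test_that("the low-pass kernel is linear phase and meets its template", {
  for (design in c("equiripple", "windowed")) {
    h <- lowpass_kernel(99, 8000, 48000, design)
    expect_length(h, 99)
    expect_max_abs(h - rev(h), 1e-12)  # type-I symmetry
  }
  # equiripple: flat to the passband edge, deep stopband
  h <- lowpass_kernel(99, 8000, 48000)
  H <- function(f) {
    vapply(f, function(ff) {
      Mod(sum(h * exp(-2i * pi * ff / 48000 * (0:98))))
    }, numeric(1))
  }
  expect_max_abs(to_db(H(seq(100, 7800, 100))), 0.05)
  expect_lt(max(to_db(H(seq(10500, 24000, 250)))), -60)
})

test_that("a diagonal delay plant is inverted to a flat response", {
  plant <- diagonal_delay_plant(c(10, 17))
  cfg <- design_config(beta = 0, fft_size = 2048, modeling_delay = 1024)
  bank <- design_filters(plant, NULL, cfg)
  expect_equal(max(abs(bank$filters)), 1)  # peak normalization is exact
  cs <- channel_separation(bank, plant, 2048)
  band <- cs$freq >= 100 & cs$freq <= 7800
  for (ch in 1:2) {
    mag_db <- 20 * log10(Mod(cs$p[band, ch, ch] * bank$level_comp))
    expect_max_abs(mag_db, 0.01)
  }
})

test_that("the design is invariant to the input scale", {
  plant <- random_plant(seed = 31, len = 48)
  scaled <- ir_set(plant$irs * 0.037, plant$sample_rate)
  cfg <- design_config(beta = 1e-3, fft_size = 512, lowpass_taps = 0,
                       modeling_delay = 256)
  b1 <- design_filters(plant, NULL, cfg)
  b2 <- design_filters(scaled, NULL, cfg)
  expect_max_abs(b1$filters - b2$filters, 1e-12)
  expect_equal(b1$total_delay, b2$total_delay)
})

test_that("design preconditions are enforced", {
  tall <- ir_set(array(rnorm(32 * 3 * 2), c(32, 3, 2)))
  expect_error(design_filters(tall, NULL, design_config(fft_size = 64)),
               "M <= L")
  expect_error(design_config(lowpass_taps = 100), "odd")
  expect_error(design_config(beta = -1), "non-negative")
  expect_error(design_config(lowpass_cutoff = 30000), "Nyquist")
})
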