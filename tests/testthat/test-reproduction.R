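test_that("targets are the low-passed plant response to the source signal", {
  plant <- random_plant(seed = 41, len = 64)
  cfg <- design_config(fft_size = 512)

  zero <- make_target(plant, 1, numeric(100), cfg)
  expect_max_abs(zero$signal$samples, 1e-15)

  # unit impulse: target equals the low-passed plant column
  imp <- make_target(plant, 2, c(1, numeric(31)), cfg)
  lp <- lowpass_kernel(99, 8000, 48000)
  for (m in 1:2) {
    expected <- ctcva:::conv_full(plant$irs[, m, 2], lp)
    got <- imp$signal$samples[seq_along(expected), m]
    expect_max_abs(got - expected, 1e-12)
  }

  # broadband input: energy above the device Nyquist is bounded by the
  # kernel's own out-of-band energy ratio (computed from its response)
  set.seed(42)
  noisy <- make_target(plant, 1, rnorm(4096) * 0.1, cfg)
  X <- Mod(ctcva:::rfft(noisy$signal$samples[, 1], 8192))^2
  f <- seq(0, 24000, length.out = length(X))
  stop_e <- sum(X[f > 8000])
  pass_e <- sum(X[f <= 8000])
  Hk <- Mod(ctcva:::rfft(lp, 8192))^2
  bound_db <- 10 * log10(sum(Hk[f > 8000]) / sum(Hk[f <= 8000]))
  expect_lt(10 * log10(stop_e / pass_e), bound_db + 3)
  # and beyond the transition band it is deeply attenuated
  expect_lt(10 * log10(sum(X[f > 10000]) / pass_e), -60)

  expect_error(make_target(plant, 9, numeric(10), cfg), "invalid source")
})

test_that("rendering is the linear map defined by the filter bank", {
  set.seed(43)
  filt <- array(rnorm(40 * 2 * 2), c(40, 2, 2))
  bank <- manual_bank(filt)

  zero <- render(binaural_target(audio_signal(matrix(0, 50, 2))), bank)
  expect_max_abs(zero$samples, 1e-15)

  # impulse on channel 1 picks out the m = 1 column of the bank
  d <- matrix(0, 1, 2); d[1, 1] <- 1
  q <- render(binaural_target(audio_signal(d)), bank)
  expect_max_abs(q$samples - filt[, , 1], 1e-15)

  dd <- audio_signal(matrix(rnorm(100), 50, 2))
  q1 <- render(binaural_target(dd), bank)
  q2 <- render(binaural_target(audio_signal(dd$samples * 2.5)), bank)
  expect_max_abs(q2$samples - 2.5 * q1$samples, 1e-12)
})

test_that("the forward path reproduces through the raw plant", {
  plant <- identity_plant()
  q0 <- audio_signal(matrix(0, 30, 2))
  expect_max_abs(forward(q0, plant)$samples, 1e-15)

  # single-path identity plant: p = q
  one <- ir_set(array(c(1, numeric(7)), c(8, 1, 1)))
  qx <- audio_signal(rnorm(25))
  expect_max_abs(forward(qx, one)$samples[1:25, 1] - qx$samples, 1e-12)

  expect_error(forward(audio_signal(matrix(0, 10, 3)), plant), "match")
})

test_that("forward(render(d)) equals convolution with composite kernels", {
  plant <- random_plant(seed = 44, len = 32)
  set.seed(45)
  filt <- array(rnorm(24 * 2 * 2), c(24, 2, 2))
  bank <- manual_bank(filt)
  d <- audio_signal(matrix(rnorm(120), 60, 2))
  p <- forward(render(binaural_target(d), bank), plant)
  # composite kernel from target channel mp to mic m
  for (m in 1:2) {
    direct <- numeric(60 + 32 + 24 - 2)
    for (mp in 1:2) {
      comp <- numeric(32 + 24 - 1)
      for (l in 1:2) {
        comp <- comp + ctcva:::conv_full(plant$irs[, m, l], filt[, l, mp])
      }
      direct <- direct + ctcva:::conv_full(comp, d$samples[, mp])
    }
    expect_max_abs(p$samples[, m] - direct, 1e-9)
  }
})

test_that("time alignment removes exactly the known constant delay", {
  set.seed(46)
  x <- matrix(rnorm(4000), ncol = 2)
  d <- audio_signal(x)
  p <- audio_signal(rbind(matrix(0, 37, 2), x))
  al <- time_align(p, d, 37, crop = 1500)
  expect_identical(al$p, al$d)
  expect_max_abs(absolute_error(al$d, al$p), 1e-15)
  expect_error(time_align(p, d, 37, crop = 10000), "too short")
  # misalignment trips the diagnostic
  expect_warning(time_align(p, d, 30, crop = 1500), "cross-correlation")
})

test_that("perfect reconstruction holds with no regularization or shaping", {
  plant <- random_plant(seed = 42, len = 64)
  N <- 1024
  cfg <- design_config(beta = 0, fft_size = N, lowpass_taps = 0,
                       modeling_delay = N / 2)
  bank <- design_filters(plant, NULL, cfg)
  for (cond in 1:2) {
    for (m in 1:2) {
      pm <- numeric(dim(bank$filters)[1] + plant$length - 1)
      for (l in 1:2) {
        pm <- pm + ctcva:::conv_full(plant$irs[, m, l], bank$filters[, l, cond])
      }
      P <- ctcva:::dtft_bins(pm * bank$level_comp, N)
      target <- if (m == cond) {
        exp(-2i * pi * (0:(N / 2)) * bank$total_delay / N)
      } else 0
      expect_max_abs(Mod(P - target), 1e-6)
    }
  }
})

test_that("recorded total delay matches the end-to-end impulse response", {
  pre <- anechoic_preset()
  plant <- simulate_hadirs(head_model_spec(), pre$room, pre$layout, 48000)
  va <- subset_spks(plant, c("L1", "R1"))
  bank <- design_filters(va, default_window(va, "anechoic"),
                         design_config(beta = 5e-4))
  e2e <- numeric(dim(bank$filters)[1] + va$length - 1)
  for (l in 1:2) {
    e2e <- e2e + ctcva:::conv_full(va$irs[, 1, l], bank$filters[, l, 1])
  }
  expect_lte(abs((which.max(abs(e2e)) - 1) - bank$total_delay), 1)
})

test_that("end-to-end reproduction of a speech-like target is accurate", {
  pre <- anechoic_preset()
  plant <- simulate_hadirs(head_model_spec(), pre$room, pre$layout, 48000)
  va <- subset_spks(plant, c("L1", "R1"))
  cfg <- design_config(beta = 5e-4)
  bank <- design_filters(va, default_window(va, "anechoic"), cfg)
  speech <- speech_like_signal(0.5, 48000, seed = 2)
  target <- make_target(plant, "L3", speech, cfg)
  rep <- reproduce(target, bank, va, crop = 20000)
  mae <- mean_absolute_error(absolute_error(rep$d, rep$p))
  # target peak is ~0.3; reproduction error sits far below the signal
  expect_lt(mae[[1]]$db, -45)
  expect_lt(mae[[2]]$db, -45)
})
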