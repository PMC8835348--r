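test_that("channel separation reports the bright-to-dark pressure ratio", {
  # hand-built system: p1 = delta, p2 = 0.01 * delta under a left impulse
  filt <- array(0, c(8, 2, 2))
  filt[1, 1, 1] <- 1     # left speaker <- left channel
  filt[1, 2, 1] <- 0.01  # right speaker leakage from left channel
  filt[1, 2, 2] <- 1
  filt[1, 1, 2] <- 0.01
  bank <- manual_bank(filt)
  cs <- channel_separation(bank, identity_plant(), 512)
  expect_max_abs(cs$cs1_db - 40, 1e-9)
  expect_max_abs(cs$cs2_db - 40, 1e-9)

  # reciprocity within a condition: 20log10|p2/p1| is exactly -cs1
  other <- 20 * (log10(Mod(cs$p[, 2, 1])) - log10(Mod(cs$p[, 1, 1])))
  expect_equal(other, -cs$cs1_db)

  # perfectly decoupled system reports the cap
  filt0 <- array(0, c(8, 2, 2))
  filt0[1, 1, 1] <- 1
  filt0[1, 2, 2] <- 1
  cs0 <- channel_separation(manual_bank(filt0), identity_plant(), 512)
  expect_true(all(cs0$cs1_db >= 120))
})

test_that("absolute and mean absolute error follow their definitions", {
  d <- matrix(c(1, 0, 0, 0, 0, 0), 3, 2)
  expect_equal(absolute_error(d, 0 * d), abs(d))
  expect_equal(absolute_error(d, -d), 2 * abs(d))
  expect_max_abs(absolute_error(d, d), 0 + 1e-15)
  expect_error(absolute_error(d, matrix(0, 2, 2)), "identical dimensions")

  ae <- rep(0.001, 500)
  m <- mean_absolute_error(ae)
  expect_equal(m$linear, 0.001)
  expect_equal(m$db, -60)

  one <- numeric(76800); one[5] <- 0.42
  expect_equal(mean_absolute_error(one)$linear, 0.42 / 76800)
  expect_error(mean_absolute_error(numeric(0)), "empty")

  # equivalence with a direct mean, and scale equivariance
  set.seed(51)
  ae2 <- abs(rnorm(10000))
  expect_equal(mean_absolute_error(ae2)$linear, mean(ae2))
  expect_equal(mean_absolute_error(3 * ae2)$db,
               mean_absolute_error(ae2)$db + to_db(3))
})

test_that("Savitzky-Golay smoothing preserves polynomials of its order", {
  const <- rep(2.5, 3000)
  expect_max_abs(smooth_ae(const) - const, 1e-9)
  ramp <- seq(0, 1, length.out = 3000)
  sm <- smooth_ae(ramp)
  interior <- 501:2500
  expect_max_abs(sm[interior] - ramp[interior], 1e-9)
  expect_length(sm, 3000)

  # linear operator
  set.seed(52)
  a <- rnorm(2000); b <- rnorm(2000)
  expect_max_abs(smooth_ae(a + b) - (smooth_ae(a) + smooth_ae(b)), 1e-9)

  expect_warning(out <- smooth_ae(numeric(10)), "shorter")
  expect_length(out, 10)
})

test_that("response analysis flags flatness and phase linearity", {
  # pure-delay system: perfectly flat, zero group-delay deviation
  filt <- array(0, c(64, 2, 2))
  filt[11, 1, 1] <- 1
  filt[11, 2, 2] <- 1
  cs <- channel_separation(manual_bank(filt), identity_plant(), 512)
  ra <- response_analysis(cs)
  expect_lt(ra$flatness_db, 1e-9)
  expect_lt(ra$group_delay_dev, 1e-6)
  expect_error(response_analysis(cs, band = c(30000, 40000)), "empty")
})

test_that("rotation sweep compares compensated and uncompensated modes", {
  expect_equal(eval(formals(rotation_sweep)$angles), -10:10)  # default grid
  pre <- anechoic_preset()
  rep <- rotation_sweep(head_model_spec(), pre$room, pre$layout,
                        design_config(beta = 5e-4, fft_size = 4096,
                                      modeling_delay = 2048),
                        angles = c(-4, 0, 4))
  s <- rep$summary
  expect_equal(nrow(s), 6)
  z <- s[s$angle == 0, ]
  expect_equal(z$cs_band_median_db[1], z$cs_band_median_db[2], tolerance = 1e-12)
  expect_equal(z$cs_band_min_db[1], z$cs_band_min_db[2], tolerance = 1e-12)
  # redesigning for the rotated head restores separation
  for (a in c(-4, 4)) {
    comp <- s[s$angle == a & s$mode == "compensated", ]
    unc <- s[s$angle == a & s$mode == "uncompensated", ]
    expect_gt(comp$cs_band_median_db, unc$cs_band_median_db)
  }
  expect_error(
    rotation_sweep(head_model_spec(), pre$room, pre$layout, angles = 15),
    "within"
  )
})
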