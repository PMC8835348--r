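hd <- head_model_spec()

test_that("a frontal source reaches both microphones identically", {
  lay <- source_layout(0, 1.5)
  p <- simulate_hadirs(hd, anechoic_preset()$room, lay, 48000, 1024)
  expect_max_abs(p$irs[, 1, 1] - p$irs[, 2, 1], 1e-12)
})

test_that("direct-path gain follows the 1/r spreading law", {
  r1 <- simulate_hadirs(hd, anechoic_preset()$room, source_layout(0, 1), 48000, 1024)
  r2 <- simulate_hadirs(hd, anechoic_preset()$room, source_layout(0, 2), 48000, 1024)
  expect_equal(max(abs(r2$irs[, 1, 1])) / max(abs(r1$irs[, 1, 1])), 0.5,
               tolerance = 0.01)
})

test_that("interaural lag for a lateral source matches the Woodworth formula", {
  # source at -90 deg, mics at -100/+100: left mic is lit at 10 deg
  # incidence, right mic shadowed at 170 deg. Closed-form lag:
  # (a/c) * (cos(10 deg) + (170 - 90) * pi/180) * fs  ~=  29.16 samples
  lay <- source_layout(-90, 1.5)
  p <- simulate_hadirs(hd, anechoic_preset()$room, lay, 48000, 2048)
  cc <- ctcva:::conv_full(p$irs[, 2, 1], rev(p$irs[, 1, 1]))
  lag <- which.max(abs(cc)) - p$length
  expected <- (0.0875 / 343) * (cos(10 * pi / 180) + 80 * pi / 180) * 48000
  expect_lte(abs(lag - expected), 1)
})

test_that("room presets encode the two testing environments", {
  an <- anechoic_preset()
  expect_equal(an$layout$distance, 1.5)
  expect_false(is.finite(an$room$tail_level_db))
  expect_true(is.null(an$room$reflections))

  bo <- booth_preset()
  expect_equal(bo$layout$distance, 1.0)
  expect_true(-90 %in% bo$layout$azimuths)           # lateral source L3
  expect_equal(bo$layout$labels[bo$layout$azimuths == -90], "L3")
  expect_equal(bo$room$tail_level_db, -50)
  nr <- nrow(bo$room$reflections)
  expect_true(nr >= 4 && nr <= 8)
  expect_true(all(abs(bo$room$reflections$gain) <= 0.3))
  expect_true(all(bo$room$reflections$delay <= 0.020))
  # the compact frontal virtual-acoustics pair
  expect_true(all(c(-15, 15) %in% bo$layout$azimuths))
})

test_that("head rotation shifts source azimuths in the head frame", {
  lay <- source_layout(c(-15, 15), 1.5)
  expect_equal(rotate_head(lay, 0)$azimuths, lay$azimuths)
  expect_max_abs(rotate_head(rotate_head(lay, 10), -10)$azimuths - lay$azimuths,
                 1e-12)
  expect_equal(rotate_head(lay, 2)$azimuths, c(-17, 13))
  expect_error(rotate_head(lay, 95), "degrees")
})

test_that("mirroring the scene swaps the microphone channels exactly", {
  bo <- booth_preset(seed = 3)
  room_m <- room_spec(
    transform(bo$room$reflections, azimuth = -azimuth),
    bo$room$tail_level_db, bo$room$tail_decay, seed = 3
  )
  lay <- bo$layout
  lay_m <- source_layout(-lay$azimuths, lay$distance, lay$labels)
  s1 <- simulate_hadirs(hd, bo$room, lay, 48000, 4096)
  s2 <- simulate_hadirs(hd, room_m, lay_m, 48000, 4096)
  expect_max_abs(s1$irs[, 1, ] - s2$irs[, 2, ], 1e-12)
  expect_max_abs(s1$irs[, 2, ] - s2$irs[, 1, ], 1e-12)
})

test_that("diffuse tail energy is calibrated to the room level", {
  lay <- source_layout(20, 1.0)
  tail_room <- room_spec(NULL, tail_level_db = -40, tail_decay = 0.1, seed = 9)
  dry_room <- room_spec(NULL, tail_level_db = -Inf)
  wet <- simulate_hadirs(hd, tail_room, lay, 48000, 8192)
  dry <- simulate_hadirs(hd, dry_room, lay, 48000, 8192)
  tail <- wet$irs[, 1, 1] - dry$irs[, 1, 1]
  ratio_db <- 10 * log10(sum(tail^2) / sum(dry$irs[, 1, 1]^2))
  expect_lt(abs(ratio_db - (-40)), 3)
})

test_that("the simulator is deterministic given its seed", {
  bo <- booth_preset(seed = 4)
  s1 <- simulate_hadirs(hd, bo$room, bo$layout, 48000, 2048)
  s2 <- simulate_hadirs(hd, bo$room, bo$layout, 48000, 2048)
  expect_identical(s1$irs, s2$irs)
})

test_that("speech-like signal has the pledged spectrum, length and level", {
  x <- speech_like_signal(1.6, 48000, seed = 1)
  expect_equal(x$n_samples, 76800)
  expect_equal(max(abs(x$samples)), 0.5, tolerance = 1e-12)
  expect_identical(speech_like_signal(1.6, 48000, 1)$samples, x$samples)

  # spectral slope between 200 Hz and 4 kHz: about -3 dB per octave
  nfft <- 131072
  X <- Mod(ctcva:::rfft(x$samples[, 1], nfft))^2
  f <- seq(0, 24000, length.out = nfft / 2 + 1)
  centers <- 200 * 2^(0:4)  # 200 ... 3200 Hz octave centers
  lev <- vapply(centers, function(fc) {
    sel <- f >= fc / 2^0.5 & f < fc * 2^0.5
    10 * log10(mean(X[sel]))
  }, numeric(1))
  slope <- stats::coef(stats::lm(lev ~ seq_along(lev)))[2]
  expect_lt(abs(slope - (-3)), 1)
})
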