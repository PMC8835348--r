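#' Channel separation of a crosstalk-cancellation system
#'
#' Feeds a unit impulse to the left and right binaural input channels (one
#' at a time, zeros to the other), propagates through the inverse filters
#' and the raw plant, and reports the frequency-dependent ratio of
#' bright-channel to dark-channel pressure:
#' \deqn{CS_1(\omega) = |p_1(\omega)/p_2(\omega)|}
#' for the left-impulse condition and
#' \eqn{CS_2(\omega) = |p_2(\omega)/p_1(\omega)|} for the right-impulse
#' condition, in dB, capped where the dark channel underflows.
#'
#' Spectra are the exact transfer values at the one-sided bin frequencies
#' of `fft_size` (alias-folded DFT of the full linear convolution).
#'
#' @param bank An inverse filter bank from [design_filters()].
#' @param plant The evaluation [ir_set()] (raw, unwindowed); its
#'   loudspeaker count must match the bank.
#' @param fft_size Evaluation FFT grid (default: the design grid).
#' @param cap_db Cap for the reported separation in dB (default 120).
#' @return An object of class `cs_curves`: `freq` (Hz), `cs1_db`, `cs2_db`,
#'   and the complex bright/dark spectra `p` (array `nbins x 2 mic x 2
#'   condition`).
#' @export
channel_separation <- function(bank, plant, fft_size = NULL, cap_db = 120) {
  stopifnot(inherits(bank, "inverse_filter_bank"), inherits(plant, "ir_set"))
  if (plant$n_spks != bank$n_spks) {
    stop("plant loudspeaker count does not match the filter bank")
  }
  if (plant$n_mics != 2 || bank$n_mics != 2) {
    stop("channel separation is defined for two microphones")
  }
  if (is.null(fft_size)) fft_size <- bank$config$fft_size
  nb <- fft_size %/% 2 + 1
  P <- array(0i, c(nb, 2, 2))  # bin x mic x impulse condition
  for (cond in 1:2) {
    for (m in 1:2) {
      pm <- numeric(dim(bank$filters)[1] + plant$length - 1)
      for (l in seq_len(bank$n_spks)) {
        pm <- pm + conv_full(plant$irs[, m, l], bank$filters[, l, cond])
      }
      if (m == cond && all(pm == 0)) {
        stop("zero reproduced signal in the bright channel: channel separation undefined")
      }
      P[, m, cond] <- dtft_bins(pm, fft_size)
    }
  }
  ratio_db <- function(bright, dark) {
    pmin(20 * (log10(Mod(bright)) - log10(Mod(dark))), cap_db)
  }
  structure(
    list(
      freq = seq(0, plant$sample_rate / 2, length.out = nb),
      cs1_db = ratio_db(P[, 1, 1], P[, 2, 1]),
      cs2_db = ratio_db(P[, 2, 2], P[, 1, 2]),
      p = P, fft_size = fft_size, sample_rate = plant$sample_rate
    ),
    class = "cs_curves"
  )
}

#' @export
print.cs_curves <- function(x, ...) {
  band <- x$freq >= 100 & x$freq <= 7800
  cat(sprintf(
    "<cs_curves> %d bins; 100-7800 Hz: min CS1 %.1f dB, min CS2 %.1f dB\n",
    length(x$freq), min(x$cs1_db[band]), min(x$cs2_db[band])
  ))
  invisible(x)
}

#' Per-sample absolute error between target and reproduced signals
#'
#' @param d,p Aligned matrices (or 2-channel signals) of equal size, as
#'   returned by [time_align()]/[reproduce()].
#' @return Matrix of per-sample absolute differences, one column per
#'   channel.
#' @export
absolute_error <- function(d, p) {
  if (inherits(d, "audio_signal")) d <- d$samples
  if (inherits(p, "audio_signal")) p <- p$samples
  d <- as.matrix(d); p <- as.matrix(p)
  if (!all(dim(d) == dim(p))) stop("`d` and `p` must have identical dimensions")
  abs(d - p)
}

#' Mean absolute error
#'
#' @param ae Numeric vector (or one column per channel) of absolute
#'   errors.
#' @return For a vector, a list with `linear` (arithmetic mean) and `db`
#'   (\eqn{20\log_{10}}); for a matrix, a list of per-column results.
#' @export
mean_absolute_error <- function(ae) {
  if (is.matrix(ae) && ncol(ae) > 1) {
    return(lapply(seq_len(ncol(ae)), function(j) mean_absolute_error(ae[, j])))
  }
  ae <- as.numeric(ae)
  if (length(ae) == 0) stop("empty error sequence")
  m <- mean(ae)
  list(linear = m, db = to_db(m))
}

#' Savitzky-Golay smoothing of an error sequence
#'
#' Window length 1001, polynomial order 1 (the presentation smoothing used
#' for absolute-error curves). Shorter sequences are passed through with a
#' warning.
#'
#' @param ae Numeric vector or matrix (one column per channel).
#' @param window Odd window length (default 1001).
#' @param order Polynomial order (default 1).
#' @return Smoothed sequence(s), same length as the input.
#' @export
smooth_ae <- function(ae, window = 1001, order = 1) {
  if (is.matrix(ae)) return(apply(ae, 2, smooth_ae, window = window, order = order))
  if (length(ae) < window) {
    warning("sequence shorter than the smoothing window; returning unsmoothed")
    return(ae)
  }
  as.numeric(signal::sgolayfilt(ae, p = order, n = window))
}

#' Magnitude flatness and phase linearity of the reproduced response
#'
#' For unit-impulse targets on each channel, examines the bright-channel
#' reproduced response over a frequency band: the maximum absolute
#' deviation of the magnitude (dB) from its band mean, and the maximum
#' deviation of the group delay (from unwrapped-phase finite differences)
#' from its band median.
#'
#' @param bank,plant,fft_size As in [channel_separation()]; a `cs_curves`
#'   object may be supplied directly as `bank` to reuse its spectra.
#' @param band Frequency band in Hz (default `c(100, 7800)`, the effective
#'   passband).
#' @return A list with `flatness_db` (max over both channels),
#'   `flatness_per_channel`, `group_delay_dev` (samples, max over both
#'   channels) and `band`.
#' @export
response_analysis <- function(bank, plant = NULL, band = c(100, 7800),
                              fft_size = NULL) {
  cs <- if (inherits(bank, "cs_curves")) bank else {
    channel_separation(bank, plant, fft_size)
  }
  sel <- cs$freq >= band[1] & cs$freq <= band[2]
  if (!any(sel)) stop("empty analysis band")
  flat <- numeric(2)
  gdev <- numeric(2)
  for (ch in 1:2) {
    spec <- cs$p[sel, ch, ch]  # bright channel of each impulse condition
    mag <- 20 * log10(Mod(spec))
    flat[ch] <- max(abs(mag - mean(mag)))
    ph <- unwrap_phase(Arg(spec))
    dw <- 2 * pi * diff(cs$freq[sel]) / cs$sample_rate
    gd <- -diff(ph) / dw  # group delay in samples
    gdev[ch] <- max(abs(gd - stats::median(gd)))
  }
  list(
    flatness_db = max(flat), flatness_per_channel = flat,
    group_delay_dev = max(gdev), band = band
  )
}

# simple phase unwrapping (no dependency on signal's masking of base funs)
unwrap_phase <- function(ph) {
  d <- diff(ph)
  jumps <- round(d / (2 * pi))
  ph - c(0, cumsum(jumps)) * 2 * pi
}

#' Head-rotation robustness sweep
#'
#' Re-simulates the plant for each head rotation angle and evaluates
#' channel separation (and optionally time-domain error against an
#' unrotated target) in two modes: \emph{uncompensated}, reusing the
#' filters designed at 0 degrees, and \emph{compensated}, redesigning the
#' filters on the rotated plant with the identical design configuration.
#'
#' @param head A [head_model_spec()].
#' @param room A [room_spec()].
#' @param layout A [source_layout()] at 0 degrees.
#' @param config A [design_config()].
#' @param angles Integer rotation angles in degrees within `[-10, 10]`
#'   (default the full 21-angle grid).
#' @param modes Character subset of `c("uncompensated", "compensated")`.
#' @param va_spks Labels/indices of the two virtual-acoustics loudspeakers
#'   used for reproduction (default `c("L1", "R1")`).
#' @param window_preset `"anechoic"` or `"booth"`: how the design window is
#'   derived (via [default_window()]) from each plant.
#' @param band Metric band in Hz.
#' @param ir_length Simulated IR length in samples (`NULL` for the preset
#'   default).
#' @param target_spk Source label for the time-domain error target
#'   (default `"L3"`); used when `include_mae = TRUE`.
#' @param include_mae Also compute per-channel mean absolute error for a
#'   speech-like target from `target_spk` (default FALSE).
#' @param speech_seed,crop Speech-like target seed and crop length.
#' @param fs Sampling rate in Hz.
#' @return An object of class `rotation_report`: a data frame `summary`
#'   with one row per (angle, mode) containing band-min and band-median of
#'   the per-bin minimum channel separation (dB) and, optionally, MAE (dB)
#'   for both channels, plus the per-run `cs` curves in `details`.
#' @export
rotation_sweep <- function(head, room, layout, config = design_config(),
                           angles = -10:10,
                           modes = c("uncompensated", "compensated"),
                           va_spks = c("L1", "R1"),
                           window_preset = c("anechoic", "booth"),
                           band = c(100, 7800), ir_length = NULL,
                           target_spk = "L3", include_mae = FALSE,
                           speech_seed = 1, crop = 76800, fs = 48000) {
  window_preset <- match.arg(window_preset)
  modes <- match.arg(modes, several.ok = TRUE)
  if (any(abs(angles) > 10) || any(angles != round(angles))) {
    stop("`angles` must be integers within [-10, 10]")
  }
  plant0 <- simulate_hadirs(head, room, layout, fs, ir_length)
  va0 <- subset_spks(plant0, va_spks)
  w0 <- default_window(va0, window_preset)
  bank0 <- design_filters(va0, w0, config)

  target <- NULL
  if (include_mae) {
    speech <- speech_like_signal(crop / fs, fs, speech_seed)
    target <- make_target(plant0, target_spk, speech, config)
  }

  rows <- list()
  details <- list()
  for (ang in angles) {
    lay_r <- rotate_head(layout, ang)
    plant_r <- simulate_hadirs(head, room, lay_r, fs, ir_length)
    va_r <- subset_spks(plant_r, va_spks)
    for (mode in modes) {
      bank <- if (mode == "uncompensated" || ang == 0) bank0 else {
        design_filters(va_r, w0, config)  # identical design parameters
      }
      cs <- channel_separation(bank, va_r, config$fft_size)
      sel <- cs$freq >= band[1] & cs$freq <= band[2]
      csmin <- pmin(cs$cs1_db[sel], cs$cs2_db[sel])
      row <- data.frame(
        angle = ang, mode = mode,
        cs_band_min_db = min(csmin),
        cs_band_median_db = stats::median(csmin)
      )
      if (include_mae) {
        rep <- reproduce(target, bank, va_r, crop = min(crop, 76800),
                         check = FALSE)
        mae <- mean_absolute_error(absolute_error(rep$d, rep$p))
        row$mae1_db <- mae[[1]]$db
        row$mae2_db <- mae[[2]]$db
      }
      rows[[length(rows) + 1]] <- row
      details[[sprintf("%s_%+03d", mode, ang)]] <- cs
    }
  }
  structure(
    list(summary = do.call(rbind, rows), details = details,
         band = band, config = config),
    class = "rotation_report"
  )
}

#' @export
print.rotation_report <- function(x, ...) {
  cat("<rotation_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export channel-separation curves as CSV
#'
#' @param cs A `cs_curves` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cs_csv <- function(cs, path) {
  stopifnot(inherits(cs, "cs_curves"))
  utils::write.csv(
    data.frame(frequency_hz = cs$freq, cs1_db = cs$cs1_db, cs2_db = cs$cs2_db),
    path, row.names = FALSE
  )
  invisible(path)
}
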