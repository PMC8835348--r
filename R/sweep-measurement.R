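#' Exponential sine sweep specification
#'
#' Parameters of an exponential (logarithmic) sine sweep used for
#' impulse-response measurement. The sweep's instantaneous frequency grows
#' exponentially from `f_start` to `f_end` over `duration` seconds, with
#' optional leading/trailing silence.
#'
#' @param f_start,f_end Sweep band edges in Hz; `0 < f_start < f_end <=`
#'   Nyquist.
#' @param duration Sweep body duration in seconds.
#' @param pre_silence,post_silence Silence padding in seconds.
#' @param amplitude Linear peak amplitude in (0, 1].
#' @param sample_rate Working sampling rate in Hz.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(f_start = 1, f_end = 24000, duration = 10,
                       pre_silence = 1, post_silence = 1,
                       amplitude = 0.5, sample_rate = 48000) {
  if (!(f_start > 0 && f_end > f_start)) stop("need 0 < f_start < f_end")
  if (f_end > sample_rate / 2) stop("`f_end` must not exceed the Nyquist frequency")
  if (duration <= 0) stop("`duration` must be positive")
  if (!(amplitude > 0 && amplitude <= 1)) stop("`amplitude` must be in (0, 1]")
  if (pre_silence < 0 || post_silence < 0) stop("silences must be non-negative")
  structure(
    list(
      f_start = f_start, f_end = f_end, duration = duration,
      pre_silence = pre_silence, post_silence = post_silence,
      amplitude = amplitude, sample_rate = sample_rate
    ),
    class = "sweep_spec"
  )
}

# sweep constants: phase(t) = K (exp(t/Tp) - 1), K = 2 pi f_start Tp
sweep_constants <- function(spec) {
  Tp <- spec$duration / log(spec$f_end / spec$f_start)
  list(Tp = Tp, K = 2 * pi * spec$f_start * Tp)
}

#' Generate an exponential sine sweep
#'
#' Produces \eqn{s(t) = A \sin(K (e^{t/T'} - 1))} with
#' \eqn{T' = T / \ln(f_2/f_1)} and \eqn{K = 2\pi f_1 T'}, padded by the
#' specified silences. The instantaneous frequency equals `f_start` at
#' \eqn{t = 0} and `f_end` at \eqn{t = T}.
#'
#' @param spec A [sweep_spec()].
#' @return A mono [audio_signal()].
#' @export
generate_ess <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  fs <- spec$sample_rate
  k <- sweep_constants(spec)
  n_body <- round(spec$duration * fs)
  t <- (seq_len(n_body) - 1) / fs
  body <- spec$amplitude * sin(k$K * (exp(t / k$Tp) - 1))
  audio_signal(
    c(numeric(round(spec$pre_silence * fs)), body,
      numeric(round(spec$post_silence * fs))),
    fs
  )
}

#' Inverse (deconvolution) filter for an exponential sine sweep
#'
#' Time-reversed sweep with a \eqn{+6} dB/octave amplitude compensation so
#' that convolving the forward sweep with it approximates a delayed unit
#' impulse (peak normalized to 1). The output has the same length as
#' [generate_ess()] output; the reversed body sits at the start, followed by
#' zeros.
#'
#' @param spec A [sweep_spec()].
#' @return A mono [audio_signal()].
#' @export
inverse_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  fs <- spec$sample_rate
  k <- sweep_constants(spec)
  n_body <- round(spec$duration * fs)
  t <- (seq_len(n_body) - 1) / fs
  body <- spec$amplitude * sin(k$K * (exp(t / k$Tp) - 1))
  # reversed sweep weighted so energy at frequency f is boosted by f/f_start
  inv <- rev(body) * exp(-t / k$Tp) * (spec$f_end / spec$f_start)
  # normalize so the self-deconvolution peak is exactly 1
  peak <- max(abs(conv_full(body, inv)))
  inv <- inv / peak
  n_total <- round((spec$pre_silence + spec$duration + spec$post_silence) * fs)
  audio_signal(c(inv, numeric(n_total - n_body)), fs)
}

# regularized frequency-domain deconvolution: recover g from
# recording = sweep (*) g. Exact (to machine precision) wherever the sweep
# spectrum is non-negligible; the tiny relative floor `eps` only guards
# spectral nulls outside the sweep band. Returns the full circular buffer
# with the zero-delay response at lag 0 (negative lags wrap to the end).
ess_deconvolve <- function(recording, fwd, eps = 1e-10) {
  N <- 2^ceiling(log2(length(recording) + length(fwd)))
  S <- stats::fft(c(fwd, numeric(N - length(fwd))))
  R <- stats::fft(c(recording, numeric(N - length(recording))))
  denom <- Mod(S)^2
  G <- R * Conj(S) / (denom + eps * max(denom))
  Re(stats::fft(G, inverse = TRUE)) / N
}

#' Extract an impulse response from a sweep recording
#'
#' Deconvolves a recording captured while the exponential sweep played
#' through the system under test, and crops the linear impulse response.
#' Deconvolution is performed by regularized frequency-domain division of
#' the zero-padded recording by the sweep spectrum, which recovers a
#' linear system exactly; the exponential sweep pushes harmonic-distortion
#' products to negative lags, which the crop excludes.
#'
#' The crop starts `margin` seconds before the anchor point. With
#' `anchor = "reference"` (default) the anchor is the zero-delay landing
#' point, so a system delay of k samples appears as a peak k samples into
#' the cropped IR and delaying the recording delays the recovered IR by
#' exactly the same amount. With `anchor = "peak"` the anchor is the
#' global peak of the deconvolved recording itself.
#'
#' @param recording Mono [audio_signal()] (or numeric vector) recorded while
#'   the sweep played.
#' @param spec The [sweep_spec()] used for playback.
#' @param ir_length Length of the cropped impulse response in samples.
#' @param margin Pre-anchor margin in seconds (default 1 ms), preserving
#'   pre-ringing.
#' @param anchor `"reference"` or `"peak"` (see Details).
#' @return Numeric vector of length `ir_length`.
#' @export
extract_ir <- function(recording, spec, ir_length, margin = 0.001,
                       anchor = c("reference", "peak")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(spec, "sweep_spec"))
  if (inherits(recording, "audio_signal")) {
    if (recording$n_channels != 1) stop("`recording` must be mono")
    if (recording$sample_rate != spec$sample_rate) stop("sample-rate mismatch")
    recording <- recording$samples[, 1]
  }
  fs <- spec$sample_rate
  n_sweep <- round(spec$duration * fs)
  if (length(recording) < n_sweep) {
    stop("recording is shorter than the sweep body")
  }
  if (all(recording == 0)) {
    warning("silent recording: returning an all-zero impulse response")
    return(numeric(ir_length))
  }
  fwd <- generate_ess(spec)$samples[, 1]
  deconv_crop(recording, fwd, spec, ir_length, margin, anchor)
}

# deconvolution + crop core (forward sweep precomputable by the caller)
deconv_crop <- function(recording, fwd, spec, ir_length, margin, anchor) {
  fs <- spec$sample_rate
  d <- ess_deconvolve(recording, fwd)
  m_samp <- round(margin * fs)
  lag0 <- if (anchor == "reference") 0L else which.max(abs(d)) - 1L
  # crop circularly so the pre-anchor margin can reach into negative lags
  idx <- ((lag0 - m_samp + seq_len(ir_length) - 1L) %% length(d)) + 1L
  d[idx]
}

#' Measure an impulse-response set by simulated sweep playback
#'
#' Emulates the in-clinic measurement protocol: for every
#' (microphone, loudspeaker) path of a known plant, the exponential sweep is
#' played through the path, optional measurement noise is added, and the
#' impulse response is recovered by deconvolution.
#'
#' Because the crop anchor precedes the true zero lag by `margin`, the
#' recovered set is a copy of the true plant uniformly delayed by
#' `round(margin * fs)` samples; that constant is returned in the
#' `"measurement_lead_in"` attribute for delay bookkeeping.
#'
#' @param plant An [ir_set()]: the system under test.
#' @param spec A [sweep_spec()].
#' @param ir_length Length of the recovered IRs (default: plant length plus
#'   the margin).
#' @param noise_db Measurement noise level in dB relative to the sweep
#'   amplitude (`-Inf` for none).
#' @param margin,anchor Passed to [extract_ir()].
#' @param seed Integer seed for the measurement noise.
#' @return An [ir_set()] of recovered impulse responses.
#' @export
measure_ir_set <- function(plant, spec, ir_length = NULL, noise_db = -Inf,
                           margin = 0.001, anchor = "reference", seed = 1) {
  stopifnot(inherits(plant, "ir_set"), inherits(spec, "sweep_spec"))
  if (plant$sample_rate != spec$sample_rate) stop("sample-rate mismatch")
  fs <- spec$sample_rate
  m_samp <- round(margin * fs)
  if (is.null(ir_length)) ir_length <- plant$length + m_samp
  fwd <- generate_ess(spec)$samples[, 1]
  out <- array(0, c(ir_length, plant$n_mics, plant$n_spks))
  set.seed(seed %% .Machine$integer.max)
  for (l in seq_len(plant$n_spks)) {
    for (m in seq_len(plant$n_mics)) {
      rec <- conv_full(fwd, plant$irs[, m, l])
      if (is.finite(noise_db)) {
        rec <- rec + stats::rnorm(length(rec)) * spec$amplitude * from_db(noise_db)
      }
      out[, m, l] <- deconv_crop(rec, fwd, spec, ir_length, margin, anchor)
    }
  }
  res <- ir_set(out, fs, plant$mic_labels, plant$spk_labels)
  attr(res, "measurement_lead_in") <- m_samp
  res
}
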