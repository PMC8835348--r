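#' Modified Tukey window specification
#'
#' A concatenation of a zero region, a raised-cosine fade-in, a flat
#' (rectangular) section, a raised-cosine fade-out and zeros — with tunable
#' fade positions and lengths. Used to temporally window measured impulse
#' responses, removing later reflections and noise that destabilize the
#' inversion.
#'
#' @param fade_in_start 0-based sample at which the fade-in begins.
#' @param fade_in_length,flat_length,fade_out_length Section lengths in
#'   samples (all non-negative).
#' @return An object of class `tukey_window_spec`.
#' @export
tukey_window_spec <- function(fade_in_start, fade_in_length, flat_length,
                              fade_out_length) {
  v <- c(fade_in_start, fade_in_length, flat_length, fade_out_length)
  if (any(v < 0)) stop("all window parameters must be non-negative")
  structure(
    list(
      fade_in_start = as.integer(fade_in_start),
      fade_in_length = as.integer(fade_in_length),
      flat_length = as.integer(flat_length),
      fade_out_length = as.integer(fade_out_length)
    ),
    class = "tukey_window_spec"
  )
}

# realize the window as a length-n vector
build_window <- function(spec, n) {
  total <- spec$fade_in_start + spec$fade_in_length + spec$flat_length +
    spec$fade_out_length
  if (total > n) stop("window (", total, " samples) exceeds the IR length (", n, ")")
  w <- numeric(n)
  i <- spec$fade_in_start
  if (spec$fade_in_length > 0) {
    k <- seq_len(spec$fade_in_length)
    w[i + k] <- 0.5 * (1 - cos(pi * k / (spec$fade_in_length + 1)))
    i <- i + spec$fade_in_length
  }
  if (spec$flat_length > 0) {
    w[i + seq_len(spec$flat_length)] <- 1
    i <- i + spec$flat_length
  }
  if (spec$fade_out_length > 0) {
    k <- seq_len(spec$fade_out_length)
    w[i + k] <- 0.5 * (1 + cos(pi * k / (spec$fade_out_length + 1)))
  }
  w
}

#' Default design window for a measured impulse-response set
#'
#' Chooses modified-Tukey parameters from the data: the fade-in ends just
#' before the earliest direct-path onset across the set; the flat section is
#' short for an anechoic measurement and extended to retain the early
#' reflections (about the first 20 ms after onset) for a reverberant booth
#' measurement, fading out before the bulk of the diffuse tail.
#'
#' @param irs An [ir_set()].
#' @param preset `"anechoic"` or `"booth"`.
#' @param onset_threshold Relative amplitude defining the onset.
#' @return A [tukey_window_spec()].
#' @export
default_window <- function(irs, preset = c("anechoic", "booth"),
                           onset_threshold = 0.005) {
  preset <- match.arg(preset)
  stopifnot(inherits(irs, "ir_set"))
  peak <- max(abs(irs$irs))
  onset <- min(apply(abs(irs$irs), c(2, 3), function(x) {
    which(x >= onset_threshold * peak)[1]
  })) - 1L  # 0-based
  fade_in <- 32L
  start <- max(0L, onset - fade_in - 8L)
  flat <- if (preset == "anechoic") 256L else {
    as.integer(round(0.025 * irs$sample_rate))  # direct + early reflections
  }
  fade_out <- if (preset == "anechoic") 128L else 256L
  # never exceed the available IR length
  avail <- irs$length - start - fade_in - fade_out
  flat <- min(flat, max(16L, avail))
  tukey_window_spec(start, fade_in, flat, fade_out)
}

#' Inverse filter design configuration
#'
#' @param beta Tikhonov regularization parameter (dimensionless,
#'   frequency-independent). 0.0005 suits an anechoic measurement, 0.001 a
#'   clinical booth.
#' @param fft_size Design FFT length in samples (even; must be at least the
#'   windowed IR length).
#' @param lowpass_taps Odd length of the linear-phase FIR low-pass applied
#'   to the filters (default 99); 0 bypasses the low-pass.
#' @param lowpass_cutoff Low-pass passband edge in Hz (default 8000, the
#'   device Nyquist).
#' @param lowpass_design `"equiripple"` (default; flat to the passband
#'   edge) or `"windowed"` (Hamming-windowed sinc, \eqn{-6} dB at the
#'   cutoff).
#' @param modeling_delay Modeling delay \eqn{\tau} in samples added for
#'   causality (default `fft_size / 2`).
#' @param peak_norm_target Peak amplitude of the final filter bank
#'   (default 1).
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `design_config`.
#' @export
design_config <- function(beta = 5e-4, fft_size = 8192, lowpass_taps = 99,
                          lowpass_cutoff = 8000,
                          lowpass_design = c("equiripple", "windowed"),
                          modeling_delay = fft_size / 2,
                          peak_norm_target = 1, sample_rate = 48000) {
  lowpass_design <- match.arg(lowpass_design)
  if (beta < 0) stop("`beta` must be non-negative")
  if (fft_size %% 2 != 0) stop("`fft_size` must be even")
  if (lowpass_taps != 0 && lowpass_taps %% 2 != 1) {
    stop("`lowpass_taps` must be odd (type-I linear phase) or 0 to bypass")
  }
  if (lowpass_cutoff > sample_rate / 2) {
    stop("`lowpass_cutoff` must not exceed the Nyquist frequency")
  }
  if (modeling_delay < 0) stop("`modeling_delay` must be non-negative")
  structure(
    list(
      beta = beta, fft_size = as.integer(fft_size),
      lowpass_taps = as.integer(lowpass_taps),
      lowpass_cutoff = lowpass_cutoff, lowpass_design = lowpass_design,
      modeling_delay = as.integer(round(modeling_delay)),
      peak_norm_target = peak_norm_target, sample_rate = sample_rate
    ),
    class = "design_config"
  )
}

#' @rdname design_config
#' @export
anechoic_design_config <- function(...) design_config(beta = 5e-4, ...)

#' @rdname design_config
#' @export
booth_design_config <- function(...) design_config(beta = 1e-3, ...)

#' Globally normalize an impulse-response set
#'
#' Scales every impulse response by one common factor so that the set's
#' maximum absolute sample is 1 (full digital dynamic range), preserving
#' all relative levels between paths.
#'
#' @param irs An [ir_set()].
#' @return The normalized [ir_set()], with the applied scale factor in
#'   attribute `"norm_scale"`.
#' @export
normalize_set <- function(irs) {
  stopifnot(inherits(irs, "ir_set"))
  peak <- max(abs(irs$irs))
  if (peak == 0) stop("cannot normalize an all-zero impulse-response set")
  out <- ir_set(irs$irs / peak, irs$sample_rate, irs$mic_labels, irs$spk_labels)
  attr(out, "norm_scale") <- 1 / peak
  out
}

#' Apply a modified Tukey window to every impulse response
#'
#' @param irs An [ir_set()].
#' @param spec A [tukey_window_spec()]; must fit within the IR length.
#' @return The windowed [ir_set()]. Samples beyond the fade-out are exactly
#'   zero.
#' @export
apply_window <- function(irs, spec) {
  stopifnot(inherits(irs, "ir_set"), inherits(spec, "tukey_window_spec"))
  w <- build_window(spec, irs$length)
  out <- irs$irs * array(w, dim(irs$irs))
  ir_set(out, irs$sample_rate, irs$mic_labels, irs$spk_labels)
}

#' Per-bin Tikhonov-regularized pseudoinverse
#'
#' For a plant bin \eqn{G} (M x L, M microphones by L loudspeakers,
#' \eqn{M \le L}) returns the minimum-norm regularized inverse
#' \deqn{H = G^H (G G^H + \beta I)^{-1},}
#' so that the loudspeaker spectra for target \eqn{d} are \eqn{H d}.
#'
#' @param G_bin Complex M x L matrix.
#' @param beta Regularization parameter, \eqn{\ge 0}. With `beta = 0` the
#'   plant must be invertible.
#' @param freq Optional frequency in Hz, used only to annotate a
#'   singularity error.
#' @return Complex L x M matrix.
#' @export
tikhonov_bin_inverse <- function(G_bin, beta, freq = NULL) {
  if (!is.matrix(G_bin)) G_bin <- as.matrix(G_bin)
  if (beta < 0) stop("`beta` must be non-negative")
  M <- nrow(G_bin)
  GH <- Conj(t(G_bin))
  A <- G_bin %*% GH + beta * diag(M)
  X <- tryCatch(
    solve(A),
    error = function(e) {
      where <- if (is.null(freq)) "" else sprintf(" at %g Hz", freq)
      stop(sprintf("singular plant with beta = 0%s: %s", where, conditionMessage(e)),
           call. = FALSE)
    }
  )
  GH %*% X
}

#' Linear-phase FIR low-pass kernel
#'
#' @param taps Odd number of taps.
#' @param cutoff Passband edge in Hz.
#' @param fs Sampling rate in Hz.
#' @param design `"equiripple"` (Parks-McClellan; stopband edge placed
#'   25 percent above the cutoff) or `"windowed"` (Hamming-windowed sinc).
#' @return Numeric vector of `taps` coefficients, symmetric about the
#'   center tap.
#' @export
lowpass_kernel <- function(taps, cutoff, fs, design = c("equiripple", "windowed")) {
  design <- match.arg(design)
  nyq <- fs / 2
  if (design == "windowed") {
    h <- signal::fir1(taps - 1, cutoff / nyq)
  } else {
    stop_edge <- min(cutoff * 1.25, (cutoff + nyq) / 2)
    h <- signal::remez(taps - 1, c(0, cutoff, stop_edge, nyq) / nyq,
                       c(1, 1, 0, 0))
  }
  as.numeric(h)
}

#' Design crosstalk-cancellation inverse filters
#'
#' Executes the eight-stage pipeline from raw impulse responses to stable,
#' causal, low-passed inverse filters realizing Tikhonov-regularized
#' pressure matching:
#' \enumerate{
#'   \item global normalization of the IR set ([normalize_set()]);
#'   \item temporal windowing ([apply_window()]);
#'   \item transform to the frequency domain ([plant_fft()]);
#'   \item per-bin regularized inversion
#'     \eqn{G^H (G G^H + \beta I)^{-1}} with the modeling-delay phase
#'     \eqn{e^{-j\omega\tau}};
#'   \item inverse transform to time-domain FIR filters;
#'   \item convolution with a linear-phase FIR low-pass;
#'   \item one global scale to a peak amplitude of `peak_norm_target`;
#'   \item a common circular shift ensuring causality and decay around each
#'     filter's main peak (shift chosen so the bank's energy centroid sits
#'     at `modeling_delay` plus the low-pass group delay).
#' }
#'
#' The returned bank records `total_delay` — the constant end-to-end delay
#' (modeling + low-pass + causal shift) to remove before comparing
#' reproduced and target signals — and `level_comp`, the exact scalar that
#' restores nominal unity passband gain end-to-end (the counterpart of
#' loudspeaker-stage gain calibration; peak normalization otherwise leaves
#' the chain with an arbitrary overall gain).
#'
#' @param irs An [ir_set()] with M microphones and L \eqn{\ge} M
#'   loudspeakers.
#' @param window A [tukey_window_spec()], or `NULL` for a rectangular
#'   window spanning the full IR (no windowing).
#' @param config A [design_config()].
#' @return An object of class `inverse_filter_bank`: `filters` (array
#'   `len x L x M`), `sample_rate`, `total_delay`, `level_comp`, `config`,
#'   `window`.
#' @export
design_filters <- function(irs, window = NULL, config = design_config()) {
  stopifnot(inherits(irs, "ir_set"), inherits(config, "design_config"))
  if (irs$n_mics > irs$n_spks) {
    stop("the design requires no more microphones than loudspeakers (M <= L)")
  }
  if (irs$sample_rate != config$sample_rate) stop("sample-rate mismatch")
  N <- config$fft_size
  tau <- config$modeling_delay

  irs_n <- normalize_set(irs)                                   # (1)
  s_norm <- attr(irs_n, "norm_scale")
  irs_w <- if (is.null(window)) irs_n else apply_window(irs_n, window)  # (2)
  P <- plant_fft(irs_w, N)                                      # (3)

  nb <- N %/% 2 + 1
  L <- irs$n_spks
  M <- irs$n_mics
  H <- array(0i, c(nb, L, M))
  phase <- exp(-2i * pi * (seq_len(nb) - 1) * tau / N)
  for (k in seq_len(nb)) {                                      # (4)
    Gk <- matrix(P$bins[k, , ], M, L)
    H[k, , ] <- tikhonov_bin_inverse(Gk, config$beta, P$freq[k]) * phase[k]
  }

  lp <- NULL
  lp_delay <- 0L
  if (config$lowpass_taps > 0) {
    lp <- lowpass_kernel(config$lowpass_taps, config$lowpass_cutoff,
                         config$sample_rate, config$lowpass_design)
    lp_delay <- (config$lowpass_taps - 1L) %/% 2L
  }
  len <- N + if (is.null(lp)) 0L else config$lowpass_taps - 1L
  filters <- array(0, c(len, L, M))
  for (l in seq_len(L)) {
    for (m in seq_len(M)) {
      h <- irfft(H[, l, m], N)                                  # (5)
      if (!is.null(lp)) h <- conv_full(h, lp)                   # (6)
      filters[, l, m] <- h
    }
  }
  if (!all(is.finite(filters))) {
    stop("inverse filters are unstable (non-finite coefficients); ",
         "increase beta or tighten the temporal window")
  }

  peak <- max(abs(filters))                                     # (7)
  s7 <- config$peak_norm_target / peak
  filters <- filters * s7

  lags <- seq_len(len) - 1                                      # (8)
  energy <- apply(filters^2, 1, sum)
  centroid <- sum(lags * energy) / sum(energy)
  ref <- tau + lp_delay
  k_shift <- as.integer(ref - round(centroid))
  if (k_shift != 0) {
    idx <- ((lags - k_shift) %% len) + 1
    filters <- filters[idx, , , drop = FALSE]
  }

  structure(
    list(
      filters = filters, sample_rate = config$sample_rate,
      n_spks = L, n_mics = M,
      total_delay = as.integer(tau + lp_delay + k_shift),
      causal_shift = k_shift,
      level_comp = s_norm / s7,
      lowpass = lp,
      config = config,
      window = window
    ),
    class = "inverse_filter_bank"
  )
}

#' @export
print.inverse_filter_bank <- function(x, ...) {
  cat(sprintf(
    "<inverse_filter_bank> %d x %d filters, %d taps @ %g Hz\n",
    x$n_spks, x$n_mics, dim(x$filters)[1], x$sample_rate
  ))
  cat(sprintf("  beta %g, fft_size %d, total_delay %d samples, level_comp %.4g\n",
              x$config$beta, x$config$fft_size, x$total_delay, x$level_comp))
  invisible(x)
}
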