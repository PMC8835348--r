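#' Multichannel audio signal
#'
#' Lightweight container for sampled audio. Samples are stored as a numeric
#' matrix with one column per channel, in a nominal full-scale range of
#' roughly \eqn{\pm 1}; bit depth is a property of file I/O only
#' (see [write_wav()]).
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel.
#' @param sample_rate Sampling rate in Hz (default 48000).
#' @return An object of class `audio_signal` with elements `samples`
#'   (matrix), `sample_rate`, `n_channels` and `n_samples`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 440 * (0:999) / 48000))
#' x$n_samples
#' @export
audio_signal <- function(samples, sample_rate = 48000) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric vector or matrix")
  }
  if (!all(is.finite(samples))) stop("all samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number")
  }
  structure(
    list(
      samples = samples,
      sample_rate = sample_rate,
      n_channels = ncol(samples),
      n_samples = nrow(samples)
    ),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal> %d channel(s), %d samples @ %g Hz (%.3f s), peak %.4g\n",
    x$n_channels, x$n_samples, x$sample_rate,
    x$n_samples / x$sample_rate, max(abs(x$samples))
  ))
  invisible(x)
}

#' Impulse-response set between loudspeakers and device microphones
#'
#' Stores the time-domain transfer paths \eqn{g_{ml}} from each of L
#' loudspeakers to each of M device microphones (the acoustic "plant"),
#' as measured by sweep deconvolution or generated by the plant simulator.
#'
#' @param irs Numeric 3-D array of dimension `c(length, M, L)`: sample index,
#'   microphone, loudspeaker.
#' @param sample_rate Sampling rate in Hz.
#' @param mic_labels,spk_labels Optional character labels; defaults are
#'   `"mic1"`, ... and `"spk1"`, ....
#' @return An object of class `ir_set`.
#' @seealso [plant_fft()], [simulate_hadirs()], [design_filters()]
#' @export
ir_set <- function(irs, sample_rate = 48000, mic_labels = NULL, spk_labels = NULL) {
  if (!is.array(irs) || length(dim(irs)) != 3 || !is.numeric(irs)) {
    stop("`irs` must be a numeric 3-D array [length x mics x loudspeakers]")
  }
  if (!all(is.finite(irs))) stop("all impulse-response samples must be finite")
  if (!is.numeric(sample_rate) || sample_rate <= 0) stop("`sample_rate` must be positive")
  M <- dim(irs)[2]
  L <- dim(irs)[3]
  if (is.null(mic_labels)) mic_labels <- paste0("mic", seq_len(M))
  if (is.null(spk_labels)) spk_labels <- paste0("spk", seq_len(L))
  stopifnot(length(mic_labels) == M, length(spk_labels) == L)
  dimnames(irs) <- list(NULL, mic_labels, spk_labels)
  structure(
    list(
      irs = irs, sample_rate = sample_rate, length = dim(irs)[1],
      n_mics = M, n_spks = L,
      mic_labels = mic_labels, spk_labels = spk_labels
    ),
    class = "ir_set"
  )
}

#' @export
print.ir_set <- function(x, ...) {
  cat(sprintf(
    "<ir_set> %d mic(s) x %d loudspeaker(s), %d samples @ %g Hz\n",
    x$n_mics, x$n_spks, x$length, x$sample_rate
  ))
  cat("  mics:", paste(x$mic_labels, collapse = ", "),
      " spks:", paste(x$spk_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Select a subset of loudspeakers from an impulse-response set
#'
#' @param irs An [ir_set()].
#' @param spks Integer indices or labels of the loudspeakers to keep.
#' @return An `ir_set` restricted to the requested loudspeaker columns.
#' @export
subset_spks <- function(irs, spks) {
  stopifnot(inherits(irs, "ir_set"))
  if (is.character(spks)) spks <- match(spks, irs$spk_labels)
  if (anyNA(spks) || any(spks < 1) || any(spks > irs$n_spks)) {
    stop("unknown loudspeaker selection")
  }
  ir_set(irs$irs[, , spks, drop = FALSE], irs$sample_rate,
         irs$mic_labels, irs$spk_labels[spks])
}

#' Amplitude ratio to decibels
#'
#' Decibel quantities throughout the package follow the amplitude
#' convention \eqn{20 \log_{10} x}.
#'
#' @param x Non-negative amplitude ratio(s). Zero maps to `-Inf`.
#' @return `20 * log10(x)`.
#' @examples
#' to_db(c(1, 0.1, 2))
#' @export
to_db <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (any(x < 0, na.rm = TRUE)) stop("`x` must be non-negative (amplitude ratio)")
  ifelse(x == 0, -Inf, 20 * log10(x))
}

#' Decibels to amplitude ratio
#' @param db Decibel value(s).
#' @return `10^(db / 20)`.
#' @export
from_db <- function(db) 10^(db / 20)

# ---- internal FFT helpers ---------------------------------------------------

# one-sided DFT of a real vector zero-padded to nfft (bins 0..nfft/2)
rfft <- function(x, nfft) {
  n <- length(x)
  if (nfft < n) stop("`nfft` must be at least the signal length")
  X <- stats::fft(c(x, numeric(nfft - n)))
  X[seq_len(nfft %/% 2 + 1)]
}

# inverse of rfft: Hermitian-symmetric synthesis back to a real vector
irfft <- function(X, nfft) {
  nb <- nfft %/% 2 + 1
  if (length(X) != nb) stop("spectrum length does not match `nfft`")
  full <- c(X, Conj(rev(X[2:(nb - 1)])))
  Re(stats::fft(full, inverse = TRUE)) / nfft
}

# exact DTFT of x sampled at the nfft-point bin frequencies, for x of any
# length: alias-fold x modulo nfft, then FFT (one-sided)
dtft_bins <- function(x, nfft) {
  n <- length(x)
  nblk <- ceiling(n / nfft)
  xp <- c(x, numeric(nblk * nfft - n))
  folded <- rowSums(matrix(xp, nrow = nfft))
  stats::fft(folded)[seq_len(nfft %/% 2 + 1)]
}

# FFT-based full linear convolution
conv_full <- function(x, h) {
  nx <- length(x); nh <- length(h)
  if (nx == 0 || nh == 0) return(numeric(0))
  n <- nx + nh - 1
  nfft <- 2^ceiling(log2(n))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - nx))) *
                       stats::fft(c(h, numeric(nfft - nh))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# ---- plant spectra ----------------------------------------------------------

#' Frequency-domain plant matrix
#'
#' Transforms an impulse-response set to the one-sided frequency domain:
#' per frequency bin, a complex M x L matrix \eqn{G(\omega)} of
#' loudspeaker-to-microphone transfer functions. The IRs are zero-padded to
#' `fft_size`; Hermitian symmetry is implied (and enforced on synthesis back
#' to the time domain).
#'
#' @param irs An [ir_set()].
#' @param fft_size Even FFT length in samples, at least the IR length.
#' @return An object of class `plant_matrix` with `bins` (complex array
#'   `nbins x M x L`), `freq` (Hz, 0 to Nyquist), `fft_size` and
#'   `sample_rate`.
#' @export
plant_fft <- function(irs, fft_size) {
  stopifnot(inherits(irs, "ir_set"))
  if (fft_size %% 2 != 0) stop("`fft_size` must be even")
  if (fft_size < irs$length) {
    stop(sprintf(
      "`fft_size` (%d) must be at least the impulse-response length (%d); truncation is not performed",
      fft_size, irs$length
    ))
  }
  nb <- fft_size %/% 2 + 1
  bins <- array(0i, c(nb, irs$n_mics, irs$n_spks))
  for (m in seq_len(irs$n_mics)) {
    for (l in seq_len(irs$n_spks)) {
      bins[, m, l] <- rfft(irs$irs[, m, l], fft_size)
    }
  }
  structure(
    list(
      bins = bins,
      freq = seq(0, irs$sample_rate / 2, length.out = nb),
      fft_size = fft_size,
      sample_rate = irs$sample_rate,
      n_mics = irs$n_mics, n_spks = irs$n_spks
    ),
    class = "plant_matrix"
  )
}

#' @export
print.plant_matrix <- function(x, ...) {
  cat(sprintf(
    "<plant_matrix> %d x %d per bin, %d bins (0-%g Hz), fft_size %d\n",
    x$n_mics, x$n_spks, length(x$freq), max(x$freq), x$fft_size
  ))
  invisible(x)
}

# ---- WAV I/O ----------------------------------------------------------------

#' Read a RIFF WAV file
#'
#' Supports PCM 16/24/32-bit integer and IEEE float32 encodings, mono or
#' multichannel. Integer samples are scaled to \eqn{[-1, 1)}.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44) stop("not a WAV file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    csz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      buf <- readBin(con, "raw", csz)
      u16 <- function(i) as.integer(buf[i]) + 256L * as.integer(buf[i + 1])
      u32 <- function(i) u16(i) + 65536 * u16(i + 2)
      fmt <- list(
        format = u16(1), channels = u16(3), rate = u32(5),
        bits = u16(15)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", csz)
    } else {
      seek(con, csz + csz %% 2, origin = "current")
      next
    }
    if (csz %% 2 == 1) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV file: ", path)
  nch <- fmt$channels
  x <- switch(
    as.character(fmt$format),
    "1" = {  # integer PCM
      bytes <- fmt$bits %/% 8
      n <- length(data_raw) %/% bytes
      v <- switch(
        as.character(fmt$bits),
        "16" = readBin(data_raw, "integer", n, 2, signed = TRUE,
                       endian = "little") / 2^15,
        "24" = {
          b <- matrix(as.integer(data_raw[seq_len(n * 3)]), nrow = 3)
          u <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
          (u - ifelse(u >= 2^23, 2^24, 0)) / 2^23
        },
        "32" = readBin(data_raw, "integer", n, 4, endian = "little") / 2^31,
        stop("unsupported PCM bit depth: ", fmt$bits)
      )
      v
    },
    "3" = readBin(data_raw, "double", length(data_raw) %/% 4, 4,
                  endian = "little"),  # IEEE float32
    stop("unsupported WAV encoding (format tag ", fmt$format, ")")
  )
  audio_signal(matrix(x, ncol = nch, byrow = TRUE), fmt$rate)
}

#' Write a RIFF WAV file
#'
#' @param signal An [audio_signal()] (or numeric vector/matrix, interpreted
#'   at `sample_rate`).
#' @param path Output path.
#' @param bit_depth One of `"pcm24"` (default), `"pcm16"`, `"float32"`.
#' @param sample_rate Used only when `signal` is not an `audio_signal`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bit_depth = c("pcm24", "pcm16", "float32"),
                      sample_rate = 48000) {
  bit_depth <- match.arg(bit_depth)
  if (!inherits(signal, "audio_signal")) signal <- audio_signal(signal, sample_rate)
  x <- t(signal$samples)  # interleave channels
  nch <- signal$n_channels
  fs <- as.integer(round(signal$sample_rate))
  v <- as.vector(x)
  if (bit_depth == "float32") {
    fmt_tag <- 3L; bits <- 32L
    data <- writeBin(v, raw(), size = 4, endian = "little")
  } else if (bit_depth == "pcm16") {
    fmt_tag <- 1L; bits <- 16L
    q <- as.integer(pmax(pmin(round(v * 2^15), 2^15 - 1), -2^15))
    data <- writeBin(q, raw(), size = 2, endian = "little")
  } else {
    fmt_tag <- 1L; bits <- 24L
    q <- pmax(pmin(round(v * 2^23), 2^23 - 1), -2^23)
    u <- q + ifelse(q < 0, 2^24, 0)
    b <- rbind(u %% 256, (u %/% 256) %% 256, (u %/% 65536) %% 256)
    data <- as.raw(as.vector(b))
  }
  block_align <- nch * bits %/% 8
  con <- file(path, "wb")
  on.exit(close(con))
  wr32 <- function(n) writeBin(as.integer(n), con, size = 4, endian = "little")
  wr16 <- function(n) writeBin(as.integer(n), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); wr32(36 + length(data))
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wr32(16)
  wr16(fmt_tag); wr16(nch); wr32(fs); wr32(fs * block_align)
  wr16(block_align); wr16(bits)
  writeChar("data", con, eos = NULL); wr32(length(data))
  writeBin(data, con)
  invisible(path)
}
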