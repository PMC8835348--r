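#' Rigid-sphere head model specification
#'
#' Geometry of the listener's head for the synthetic plant: a rigid sphere
#' with two behind-the-ear device microphones on its surface. Interaural
#' time differences follow the Woodworth construction (straight ray to the
#' lit side, arc along the sphere on the shadowed side) and head shadow is
#' modeled as a first-order low-pass whose cutoff falls with incidence
#' angle behind the head.
#'
#' @param radius Sphere radius in meters (default 0.0875, an average adult
#'   head).
#' @param mic_azimuths Microphone azimuths in degrees on the head surface;
#'   positive right, 0 front. Defaults to `c(-100, 100)` (behind-the-ear
#'   positions).
#' @param speed_of_sound In m/s (default 343).
#' @param shadow_cutoff_open Shadow low-pass cutoff in Hz on the lit side
#'   (effectively transparent).
#' @param shadow_cutoff_back Cutoff in Hz when the source is diametrically
#'   opposite the microphone. Between 90 and 180 degrees of incidence the
#'   \emph{inverse} cutoff is interpolated linearly, which matches the
#'   growth of rigid-sphere shadow-zone attenuation with incidence angle
#'   (about 3 dB at 115 degrees and 6 dB at 135 degrees near 4 kHz for an
#'   8.75 cm sphere).
#' @return An object of class `head_model_spec`.
#' @export
head_model_spec <- function(radius = 0.0875, mic_azimuths = c(-100, 100),
                            speed_of_sound = 343,
                            shadow_cutoff_open = 16000,
                            shadow_cutoff_back = 2200) {
  if (radius <= 0) stop("`radius` must be positive")
  if (speed_of_sound <= 0) stop("`speed_of_sound` must be positive")
  structure(
    list(
      radius = radius, mic_azimuths = mic_azimuths,
      speed_of_sound = speed_of_sound,
      shadow_cutoff_open = shadow_cutoff_open,
      shadow_cutoff_back = shadow_cutoff_back
    ),
    class = "head_model_spec"
  )
}

#' Room specification for the plant simulator
#'
#' @param reflections Data frame with one row per reflecting surface,
#'   columns `delay` (s, nominal extra path delay for a source facing the
#'   surface — the surface distance is derived from it at simulation time),
#'   `gain` (linear reflectance, `abs(gain) < 1`) and `azimuth` (degrees,
#'   direction of the surface normal from the head). Each loudspeaker is
#'   mirrored across each surface (first-order image sources), so arrival
#'   times and directions differ per loudspeaker as they do physically.
#'   `NULL` for none.
#' @param tail_level_db Energy of the diffuse reverberant tail in dB
#'   relative to the direct-path energy (`-Inf` for anechoic).
#' @param tail_decay Exponential decay time constant of the tail in
#'   seconds.
#' @param seed Integer seed making the tail realization deterministic.
#' @return An object of class `room_spec`.
#' @export
room_spec <- function(reflections = NULL, tail_level_db = -Inf,
                      tail_decay = 0.15, seed = 1) {
  if (!is.null(reflections)) {
    stopifnot(is.data.frame(reflections),
              all(c("delay", "gain", "azimuth") %in% names(reflections)))
    if (any(reflections$delay <= 0)) stop("reflection delays must be positive")
    if (any(abs(reflections$gain) >= 1)) stop("reflection |gain| must be < 1")
  }
  if (tail_level_db > 0) stop("`tail_level_db` must be <= 0 dB")
  if (tail_decay <= 0) stop("`tail_decay` must be positive")
  structure(
    list(
      reflections = reflections, tail_level_db = tail_level_db,
      tail_decay = tail_decay, seed = as.integer(seed)
    ),
    class = "room_spec"
  )
}

#' Loudspeaker layout
#'
#' @param azimuths Loudspeaker azimuths in degrees (positive right, 0
#'   front), within `[-180, 180)`.
#' @param distance Distance from head center in meters.
#' @param labels Optional loudspeaker labels.
#' @return An object of class `source_layout`.
#' @export
source_layout <- function(azimuths, distance, labels = NULL) {
  if (distance <= 0) stop("`distance` must be positive")
  if (any(azimuths < -180 | azimuths >= 180)) {
    stop("azimuths must lie in [-180, 180)")
  }
  if (is.null(labels)) labels <- paste0("spk", seq_along(azimuths))
  stopifnot(length(labels) == length(azimuths))
  structure(
    list(azimuths = azimuths, distance = distance, labels = labels,
         n = length(azimuths)),
    class = "source_layout"
  )
}

#' Anechoic and booth presets
#'
#' Study conditions for the two testing environments: a heavily treated
#' anechoic room (direct sound only, sources at 1.5 m) and a small
#' audiological testing booth with moderate treatment (first-order early
#' reflections within 20 ms, a low-level diffuse tail at \eqn{-50} dB with
#' 0.15 s decay, sources at 1.0 m). Both use a six-loudspeaker semicircle:
#' a compact frontal virtual-acoustics pair L1/R1 at \eqn{\pm 15^\circ},
#' flanking pairs at \eqn{\pm 50^\circ}, and lateral sources L3/R3 at
#' \eqn{\pm 90^\circ}.
#'
#' @param seed Integer seed for the booth's diffuse tail.
#' @return A list with elements `room` ([room_spec()]) and `layout`
#'   ([source_layout()]).
#' @export
anechoic_preset <- function(seed = 1) {
  list(
    room = room_spec(NULL, tail_level_db = -Inf, seed = seed),
    layout = source_layout(
      c(-90, -50, -15, 15, 50, 90), 1.5,
      c("L3", "L2", "L1", "R1", "R2", "R3")
    )
  )
}

#' @rdname anechoic_preset
#' @export
booth_preset <- function(seed = 1) {
  refl <- data.frame(
    delay   = c(0.0020, 0.0035, 0.0040, 0.0040, 0.0060, 0.0060, 0.0080, 0.0080),
    gain    = c(0.25,   0.20,   0.18,   0.18,   0.14,   0.14,   0.10,  -0.10),
    azimuth = c(0,      -180,   90,     -90,    45,     -45,    135,   -135)
  )
  list(
    room = room_spec(refl, tail_level_db = -50, tail_decay = 0.15, seed = seed),
    layout = source_layout(
      c(-90, -50, -15, 15, 50, 90), 1.0,
      c("L3", "L2", "L1", "R1", "R2", "R3")
    )
  )
}

#' Rotate the head relative to a loudspeaker layout
#'
#' A head rotation by `angle` degrees (positive to the right) is expressed
#' in the head-relative frame by shifting every source azimuth by
#' `-angle`.
#'
#' @param layout A [source_layout()].
#' @param angle Rotation in degrees, `abs(angle) <= 90`.
#' @return The rotated [source_layout()].
#' @export
rotate_head <- function(layout, angle) {
  stopifnot(inherits(layout, "source_layout"))
  if (abs(angle) > 90) stop("`angle` must be within [-90, 90] degrees")
  az <- layout$azimuths - angle
  az <- ((az + 180) %% 360) - 180
  source_layout(az, layout$distance, layout$labels)
}

# wrapped absolute angular separation in degrees, in [0, 180]
ang_sep <- function(a, b) {
  d <- abs(((a - b + 180) %% 360) - 180)
  d
}

# Woodworth per-microphone delay offset (s) relative to head-center arrival,
# for angular separation D (deg) between source and microphone azimuths
woodworth_offset <- function(D, radius, c0) {
  Dr <- D * pi / 180
  ifelse(D <= 90, -radius / c0 * cos(Dr), radius / c0 * (Dr - pi / 2))
}

# 32-tap Hann-windowed sinc kernel realizing a fractional delay;
# returns list(offset = integer lag of kernel[1], kernel)
frac_delay_kernel <- function(delay_samples, n_taps = 32) {
  i0 <- floor(delay_samples) - n_taps / 2 + 1
  n <- seq.int(i0, length.out = n_taps)
  x <- n - delay_samples
  k <- ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  w <- 0.5 * (1 + cos(pi * x / (n_taps / 2)))
  w[abs(x) > n_taps / 2] <- 0
  list(offset = i0, kernel = k * w)
}

# zero-phase first-order low-pass (forward-backward one-pole), unit DC gain
shadow_lowpass <- function(x, fc, fs) {
  if (fc >= fs / 2) return(x)
  a <- exp(-2 * pi * fc / fs)
  y <- stats::filter(x * (1 - a), a, method = "recursive")
  y <- rev(stats::filter(rev(y) * (1 - a), a, method = "recursive"))
  as.numeric(y)
}

# single propagation path through the head model: windowed-sinc fractional
# delay at `delay` seconds, amplitude `gain`, head-shadowed for angular
# separation D
path_component <- function(delay, gain, D, head, fs, n) {
  fd <- frac_delay_kernel(delay * fs)
  out <- numeric(n)
  idx <- fd$offset + seq_along(fd$kernel)  # 0-based lags + 1 == 1-based index
  ok <- idx >= 1 & idx <= n
  if (!any(ok)) stop("impulse-response length too short to contain this path")
  out[idx[ok]] <- gain * fd$kernel[ok]
  fc <- if (D <= 90) head$shadow_cutoff_open else {
    # linear interpolation of the inverse cutoff between the lit-side and
    # diametric values: attenuation grows ~linearly with angle behind 90 deg
    1 / ((1 - (D - 90) / 90) / head$shadow_cutoff_open +
           ((D - 90) / 90) / head$shadow_cutoff_back)
  }
  shadow_lowpass(out, fc, fs)
}

#' Simulate device-microphone impulse responses
#'
#' Synthetic stand-in for in-situ sweep measurement of a head-and-torso
#' simulator fitted with behind-the-ear devices: for every
#' (microphone, loudspeaker) pair the direct path is rendered with
#' \eqn{1/r} spreading, Woodworth rigid-sphere interaural delay and
#' angle-dependent head-shadow low-pass; each early reflection is processed
#' as an image source through the same head model; an optional seeded
#' exponentially decaying diffuse tail is added at the room's
#' `tail_level_db`. Deterministic given the room seed.
#'
#' @param head A [head_model_spec()].
#' @param room A [room_spec()].
#' @param layout A [source_layout()].
#' @param fs Sampling rate in Hz.
#' @param length IR length in samples; must accommodate the direct path.
#' @return An [ir_set()] of dimension `length x 2 x L`.
#' @export
simulate_hadirs <- function(head, room, layout, fs = 48000, length = NULL) {
  stopifnot(inherits(head, "head_model_spec"), inherits(room, "room_spec"),
            inherits(layout, "source_layout"))
  c0 <- head$speed_of_sound
  r <- layout$distance
  M <- length(head$mic_azimuths)
  if (is.null(length)) {
    length <- if (is.finite(room$tail_level_db) || !is.null(room$reflections)) {
      8192L
    } else {
      2048L
    }
  }
  n <- as.integer(length)
  direct_lag <- (r / c0 - head$radius / c0) * fs
  if (n < direct_lag + 32) {
    stop("`length` too short to contain the direct path")
  }
  irs <- array(0, c(n, M, layout$n))
  t <- (seq_len(n) - 1) / fs
  for (l in seq_len(layout$n)) {
    az <- layout$azimuths[l]
    # interaurally coherent tail realization, shared by both microphones
    tail_noise <- NULL
    if (is.finite(room$tail_level_db)) {
      set.seed((room$seed * 1000003L + l * 7919L) %% .Machine$integer.max)
      tail_noise <- stats::rnorm(n)
    }
    # first-order image of this loudspeaker across each reflecting surface
    images <- NULL
    if (!is.null(room$reflections)) {
      azr <- az * pi / 180
      p_src <- r * c(cos(azr), sin(azr))  # x front, y right
      images <- lapply(seq_len(nrow(room$reflections)), function(k) {
        rf <- room$reflections[k, ]
        d_wall <- r + c0 * rf$delay / 2  # nominal surface distance
        nr <- rf$azimuth * pi / 180
        nvec <- c(cos(nr), sin(nr))
        p_img <- p_src + 2 * (d_wall - sum(p_src * nvec)) * nvec
        r_img <- sqrt(sum(p_img^2))
        list(
          azimuth = atan2(p_img[2], p_img[1]) * 180 / pi,
          distance = r_img,
          gain = rf$gain / r_img
        )
      })
    }
    for (m in seq_len(M)) {
      D <- ang_sep(az, head$mic_azimuths[m])
      delay <- r / c0 + woodworth_offset(D, head$radius, c0)
      direct <- path_component(delay, 1 / r, D, head, fs, n)
      g <- direct
      for (img in images) {
        Dr <- ang_sep(img$azimuth, head$mic_azimuths[m])
        dl <- img$distance / c0 + woodworth_offset(Dr, head$radius, c0)
        g <- g + path_component(dl, img$gain, Dr, head, fs, n)
      }
      if (!is.null(tail_noise)) {
        t0 <- r / c0 + 0.002  # tail begins just after the direct arrival
        env <- ifelse(t >= t0, exp(-(t - t0) / room$tail_decay), 0)
        tail <- tail_noise * env
        e_direct <- sum(direct^2)
        e_tail <- sum(tail^2)
        if (e_tail > 0) {
          tail <- tail * sqrt(e_direct / e_tail) * from_db(room$tail_level_db)
          g <- g + tail
        }
      }
      irs[, m, l] <- g
    }
  }
  ir_set(irs, fs, c("left", "right")[seq_len(M)], layout$labels)
}

#' Speech-like test signal
#'
#' Deterministic stand-in for a recorded speech sample: pink-spectrum noise
#' (\eqn{-3} dB/octave) with 4 Hz amplitude modulation and brief pauses,
#' peak-normalized to 0.5.
#'
#' @param duration Duration in seconds (default 1.6, i.e. 76,800 samples at
#'   48 kHz).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @return A mono [audio_signal()].
#' @export
speech_like_signal <- function(duration = 1.6, fs = 48000, seed = 1) {
  if (duration <= 0) stop("`duration` must be positive")
  n <- round(duration * fs)
  set.seed(seed %% .Machine$integer.max)
  nfft <- 2^ceiling(log2(n))
  white <- stats::rnorm(nfft)
  X <- rfft(white, nfft)
  f <- seq(0, fs / 2, length.out = length(X))
  shape <- c(0, 1 / sqrt(f[-1]))  # -3 dB/octave amplitude slope, no DC
  x <- irfft(X * shape, nfft)[seq_len(n)]
  t <- (seq_len(n) - 1) / fs
  am <- 0.15 + 0.85 * (0.5 + 0.5 * sin(2 * pi * 4 * t))
  # smooth pauses from a slow oscillation gate
  p <- sin(2 * pi * 0.7 * t + 2)
  gate <- pmin(1, pmax(0, (p + 0.95) / 0.25))
  x <- x * am * gate
  audio_signal(0.5 * x / max(abs(x)), fs)
}
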