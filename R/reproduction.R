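#' Binaural target signal
#'
#' Two-channel target pressure signal \eqn{d[n]} to be reproduced at the
#' device microphones.
#'
#' @param signal A 2-channel [audio_signal()].
#' @param provenance Free-form description (e.g. source label and the plant
#'   it was rendered from).
#' @return An object of class `binaural_target`.
#' @export
binaural_target <- function(signal, provenance = "") {
  stopifnot(inherits(signal, "audio_signal"))
  if (signal$n_channels != 2) stop("a binaural target must have exactly 2 channels")
  structure(list(signal = signal, provenance = provenance),
            class = "binaural_target")
}

#' Create a binaural target from a single loudspeaker
#'
#' Emulates the target-creation protocol: a mono signal played from one
#' loudspeaker of the (unwindowed) plant and recorded at both device
#' microphones, then filtered with the same low-pass applied to the inverse
#' filters so that energy beyond the device Nyquist is negligible.
#'
#' @param plant An [ir_set()].
#' @param source Loudspeaker index or label within `plant`.
#' @param signal Mono [audio_signal()] (or numeric vector at the plant
#'   rate).
#' @param config A [design_config()] providing the low-pass kernel; use
#'   `lowpass_taps = 0` to bypass.
#' @return A [binaural_target()].
#' @export
make_target <- function(plant, source, signal, config = design_config()) {
  stopifnot(inherits(plant, "ir_set"))
  if (is.character(source)) source <- match(source, plant$spk_labels)
  if (is.na(source) || source < 1 || source > plant$n_spks) {
    stop("invalid source index/label")
  }
  if (!inherits(signal, "audio_signal")) {
    signal <- audio_signal(signal, plant$sample_rate)
  }
  if (signal$n_channels != 1) stop("`signal` must be mono")
  if (signal$sample_rate != plant$sample_rate) stop("sample-rate mismatch")
  x <- signal$samples[, 1]
  lp <- if (config$lowpass_taps > 0) {
    lowpass_kernel(config$lowpass_taps, config$lowpass_cutoff,
                   config$sample_rate, config$lowpass_design)
  } else NULL
  d <- sapply(seq_len(plant$n_mics), function(m) {
    y <- conv_full(plant$irs[, m, source], x)
    if (!is.null(lp)) y <- conv_full(y, lp)
    y
  })
  binaural_target(audio_signal(d, plant$sample_rate),
                  provenance = sprintf("source %s", plant$spk_labels[source]))
}

#' Render loudspeaker signals from a binaural target
#'
#' Full linear convolution of the target channels with the inverse filter
#' bank: \eqn{q_l[n] = \sum_m h_{lm} * d_m}.
#'
#' @param target A [binaural_target()] (or 2-channel [audio_signal()]).
#' @param bank An [inverse_filter_bank()][design_filters()].
#' @return An L-channel [audio_signal()] of loudspeaker signals.
#' @export
render <- function(target, bank) {
  stopifnot(inherits(bank, "inverse_filter_bank"))
  sig <- if (inherits(target, "binaural_target")) target$signal else target
  stopifnot(inherits(sig, "audio_signal"))
  if (sig$sample_rate != bank$sample_rate) stop("sample-rate mismatch")
  if (sig$n_channels != bank$n_mics) {
    stop("target channel count does not match the filter bank")
  }
  nlen <- sig$n_samples + dim(bank$filters)[1] - 1
  q <- matrix(0, nlen, bank$n_spks)
  for (l in seq_len(bank$n_spks)) {
    for (m in seq_len(bank$n_mics)) {
      q[, l] <- q[, l] + conv_full(bank$filters[, l, m], sig$samples[, m])
    }
  }
  audio_signal(q, bank$sample_rate)
}

#' Propagate loudspeaker signals through the acoustic plant
#'
#' Physical forward path: \eqn{p_m[n] = \sum_l g_{ml} * q_l} using the raw
#' (unwindowed) plant.
#'
#' @param q An L-channel [audio_signal()] of loudspeaker signals.
#' @param plant An [ir_set()] whose loudspeaker count equals the channel
#'   count of `q`.
#' @return An M-channel [audio_signal()] of reproduced microphone pressure
#'   signals.
#' @export
forward <- function(q, plant) {
  stopifnot(inherits(q, "audio_signal"), inherits(plant, "ir_set"))
  if (q$sample_rate != plant$sample_rate) stop("sample-rate mismatch")
  if (q$n_channels != plant$n_spks) {
    stop("loudspeaker channel count does not match the plant")
  }
  nlen <- q$n_samples + plant$length - 1
  p <- matrix(0, nlen, plant$n_mics)
  for (m in seq_len(plant$n_mics)) {
    for (l in seq_len(plant$n_spks)) {
      p[, m] <- p[, m] + conv_full(plant$irs[, m, l], q$samples[, l])
    }
  }
  audio_signal(p, plant$sample_rate)
}

#' Time-align reproduced and target signals
#'
#' Advances the reproduced signal by the known constant delay (modeling
#' delay + low-pass group delay + causal shift, as recorded by the filter
#' bank) and crops both signals to a common length. Alignment is
#' deterministic; a cross-correlation check is run as a diagnostic and a
#' warning is emitted if its argmax disagrees with the known delay.
#'
#' @param p Reproduced M-channel [audio_signal()].
#' @param d Target [binaural_target()] or [audio_signal()].
#' @param total_delay Constant delay in samples (e.g. `bank$total_delay`).
#' @param crop Output length in samples (default 76800, i.e. 1.6 s at
#'   48 kHz).
#' @param check Run the cross-correlation diagnostic (default TRUE).
#' @return A list with aligned `p` and `d` matrices (`crop` x M).
#' @export
time_align <- function(p, d, total_delay, crop = 76800, check = TRUE) {
  stopifnot(inherits(p, "audio_signal"))
  dsig <- if (inherits(d, "binaural_target")) d$signal else d
  stopifnot(inherits(dsig, "audio_signal"))
  if (total_delay < 0) stop("`total_delay` must be non-negative")
  if (p$n_samples - total_delay < crop || dsig$n_samples < crop) {
    stop("signals too short for the requested crop after delay removal")
  }
  pa <- p$samples[total_delay + seq_len(crop), , drop = FALSE]
  da <- dsig$samples[seq_len(crop), , drop = FALSE]
  if (check) {
    x <- da[, 1]; y <- pa[, 1]
    cc <- conv_full(y, rev(x))
    lag <- which.max(abs(cc)) - length(x)
    if (abs(lag) > 1 && max(abs(x)) > 0) {
      warning(sprintf(
        "cross-correlation argmax disagrees with the known delay by %d samples",
        lag
      ))
    }
  }
  list(p = pa, d = da)
}

#' End-to-end reproduction of a binaural target
#'
#' Convenience wrapper: renders the target through the inverse filters,
#' propagates through the (raw) plant, applies the bank's exact level
#' compensation (the counterpart of loudspeaker-stage gain calibration) and
#' time-aligns against the target.
#'
#' @param target A [binaural_target()].
#' @param bank An inverse filter bank from [design_filters()].
#' @param plant The evaluation [ir_set()] (raw, unwindowed).
#' @param crop Crop length in samples; `NULL` for the maximum available.
#' @param extra_delay Signed adjustment in samples added to the bank delay
#'   during alignment (e.g. `-lead_in` when the design plant was measured
#'   with a sweep pre-peak margin and therefore trails the true plant).
#' @param check Passed to [time_align()]'s cross-correlation diagnostic.
#' @return A list with `p`, `d` (aligned matrices), `q` (loudspeaker
#'   signals) and `total_delay`.
#' @export
reproduce <- function(target, bank, plant, crop = 76800, extra_delay = 0,
                      check = TRUE) {
  q <- render(target, bank)
  p <- forward(q, plant)
  p <- audio_signal(p$samples * bank$level_comp, p$sample_rate)
  delay <- bank$total_delay + extra_delay
  dn <- if (inherits(target, "binaural_target")) target$signal$n_samples
        else target$n_samples
  if (is.null(crop)) crop <- min(p$n_samples - delay, dn)
  al <- time_align(p, target, delay, crop, check = check)
  list(p = al$p, d = al$d, q = q, total_delay = delay)
}
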