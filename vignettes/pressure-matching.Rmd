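---
title: "Pressure-matched virtual acoustics at hearing-device microphones: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure-matched virtual acoustics at hearing-device microphones: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcva)
```

## The problem

Clinical assessment of spatial hearing in users of hearing-assistive
devices (HADs: hearing aids, cochlear-implant processors) conventionally
requires a large loudspeaker array in a heavily treated room. An
alternative is a compact virtual-acoustics system: two loudspeakers plus
inverse filters that control the sound pressure directly *at the device
microphones*, so that the microphones receive the same signals they would
receive from a real source anywhere in space. `ctcva` implements this
system end to end in simulation-capable form: transfer-path measurement,
inverse-filter design, rendering, and physical-accuracy evaluation.

## The model

Everything happens per frequency. Let \(G(\omega) \in \mathbb{C}^{M
\times L}\) collect the electroacoustic transfer functions from \(L\)
loudspeakers to \(M\) device microphones (here \(M = 2\), one behind each
ear, and \(L = 2\) for the reproduction pair). For a target microphone
pressure vector \(d(\omega)\) we seek loudspeaker signals \(q(\omega)\)
with \(G q \approx d\). The filters solve the Tikhonov-regularized
pressure-matching (crosstalk-cancellation) problem in minimum-norm form:

\[
q_0(\omega) = G^{\mathsf H}(\omega)\,
  \bigl(G(\omega) G^{\mathsf H}(\omega) + \beta I\bigr)^{-1}
  d(\omega)\, e^{-j\omega\tau},
\]

where \(\beta \ge 0\) is a frequency-independent regularization parameter
and \(\tau\) a modeling delay that buys causality for the mixed-phase
inverse. The reproduced pressure is then \(p = G q_0 \approx d\,
e^{-j\omega\tau}\). Regularization trades exactness for bounded
loudspeaker effort and stability; the residual coupling it leaves between
the two microphone channels is what the channel-separation metric
measures.

`tikhonov_bin_inverse()` implements the per-bin solve exactly as written
(a dense Hermitian solve; no switch to the overdetermined form — the
design enforces \(M \le L\)). With \(\beta = 0\) and an invertible plant
the package reproduces a delayed copy of the target to machine precision;
this perfect-reconstruction limit is pinned by a test.

## The design pipeline

`design_filters()` runs eight stages, in order:

1. **Global normalization** (`normalize_set()`): one common scale makes
   the IR set's peak 1, using the full digital dynamic range without
   touching inter-path level ratios.
2. **Temporal windowing** (`apply_window()`): a modified Tukey window
   (zeros, raised-cosine fade-in, flat section, raised-cosine fade-out,
   zeros) removes late reflections and noise that destabilize the
   inversion. `default_window()` derives parameters from the data: the
   fade-in ends just before the earliest onset; the flat section is 256
   samples for an anechoic measurement and 25 ms for a booth measurement
   (long enough to *retain* the early reflections, which the inversion
   then equalizes), fading out before the bulk of the diffuse tail.
3. **FFT** (`plant_fft()`), one-sided storage with Hermitian synthesis.
4. **Per-bin regularized inversion** with the modeling-delay phase.
5. **Inverse FFT** to time-domain FIR filters.
6. **Low-pass filtering**: a 99-tap linear-phase FIR with passband edge
   8000 Hz (the HAD Nyquist — devices sample at 16 kHz), suppressing
   inversion energy where the device microphone response rolls off.
7. **Peak normalization** of the whole bank to 1.
8. **Causal shift**: a common circular shift placing the bank's energy
   centroid at \(\tau\) + the low-pass group delay, guaranteeing decay on
   both sides of the main peaks.

The bank records `total_delay` (modeling delay + low-pass group delay +
causal shift), which `time_align()` removes before any time-domain
comparison, and `level_comp`, the exact scalar restoring end-to-end unity
gain (peak normalization leaves the chain with an arbitrary overall
gain; in hardware this is absorbed by loudspeaker-stage calibration, and
`reproduce()` plays that role here).

### Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `beta` | 5e-4 (anechoic), 1e-3 (booth) | The booth's richer, partly truncated plant needs more regularization for stability. |
| `fft_size` | 8192 samples (~171 ms at 48 kHz) | Must exceed the windowed IR length; 8192 leaves the regularized inverse's pre/post-ring far from wrap-around. |
| `modeling_delay` | `fft_size / 2` | Centers the mixed-phase inverse in the buffer — the standard choice when nothing else is known. |
| `lowpass_taps`, `lowpass_cutoff` | 99 taps, 8000 Hz | Device Nyquist; odd length keeps type-I linear phase. |
| sampling rate | 48 kHz | Measurement-system rate; device-rate resampling is out of scope. |

The low-pass kernel is equiripple (Parks–McClellan) by default, flat to
the 8000 Hz passband edge with a stopband from 10 kHz at about
\(-72\) dB. A Hamming-windowed design (−6 dB *at* the cutoff) is
available via `lowpass_design = "windowed"`, but it already droops more
than 3 dB at 7800 Hz, which would dominate every passband-flatness
figure; the equiripple reading of "cutoff" is the one consistent with
sub-dB flatness across a 100–7800 Hz passband, so it is the default.

## Sweep measurement

In-clinic transfer functions are measured with an exponential sine sweep
\(s(t) = \sin\!\bigl(K(e^{t/T'}-1)\bigr)\), \(T' = T/\ln(f_2/f_1)\),
\(K = 2\pi f_1 T'\), swept 1 Hz–24 kHz (`generate_ess()`). Defaults use a
10 s sweep with 1 s of surrounding silence; longer sweeps raise SNR.
`extract_ir()` deconvolves the recording by regularized frequency-domain
division with the sweep spectrum — exact for a linear system, with a tiny
relative floor (1e-10) guarding spectral nulls outside the sweep band.
The classic time-reversed, amplitude-compensated inverse sweep is
provided as `inverse_sweep()`; note its amplitude compensation is
asymptotic, so its self-deconvolution kernel carries roughly −55 dB
sidelobes — fine for inspection, but the spectral division is what the
measurement path uses, and it recovers a known 256-tap system below
−130 dB error. The exponential sweep pushes harmonic distortion to
negative lags, which the crop excludes.

The crop anchor is the zero-delay landing point minus a 1 ms pre-peak
margin (preserving pre-ringing), so delaying the recording by \(k\)
samples delays the recovered IR by exactly \(k\) — the property that
makes delay bookkeeping exact downstream. Anchoring at the measurement's
own global peak (`anchor = "peak"`) is available but breaks that
shift-equivariance, which is why it is not the default. Measured sets
carry the margin as a known uniform lead-in, returned as an attribute
and subtracted during scenario alignment.

## The plant simulator

`simulate_hadirs()` stands in for a head-and-torso manikin fitted with
behind-the-ear devices in a real room. It is deliberately simple enough
to be analytically checkable:

* **Geometry**: microphones at ±100° on a rigid sphere of radius
  8.75 cm; sources on a semicircle at 1.5 m (anechoic preset) or 1.0 m
  (booth preset), six positions from −90° (L3) to +90° with the
  virtual-acoustics pair at ±15° — a compact frontal pair, configurable.
* **Direct path**: delay \(r/c\) plus the Woodworth rigid-sphere offset
  (straight ray on the lit side, arc along the sphere behind it), gain
  \(1/r\), fractional delays realized by 32-tap windowed-sinc
  interpolation so interaural delays are not quantized to samples.
* **Head shadow**: a zero-phase first-order low-pass whose cutoff falls
  from 16 kHz (lit) to 2.2 kHz (diametric), interpolated linearly in
  *inverse* cutoff, calibrated to rigid-sphere shadow-zone attenuation
  (≈3 dB at 115° and ≈6 dB at 135° of incidence near 4 kHz). Zero-phase
  application keeps interaural *time* differences purely Woodworth. An
  early draft interpolated the cutoff itself, leaving near-zero
  interaural level difference at 4 kHz; that made the plant singular at
  the frequency where the interaural phase difference reaches π — an
  artifact no physical head produces — and was corrected.
* **Reflections** (booth): each loudspeaker is mirrored across each
  reflecting surface (first-order image sources), so reflection arrival
  times and directions differ per loudspeaker as they must physically.
  A draft that added one shared reflection pattern to all loudspeakers
  made the plant columns share an identical additive term —
  rank-deficient at comb frequencies — and was likewise corrected. The
  booth preset uses eight surfaces with reflectances ≤ 0.25 and nominal
  extra delays of 2–8 ms, plausible for a 2.5 m × 2.1 m treated booth.
* **Diffuse tail** (booth): seeded exponentially decaying noise at
  −50 dB total energy relative to the direct path, 0.15 s decay. The
  tail is shared between the two microphones (interaurally coherent);
  real diffuse fields decorrelate above a few hundred hertz, so this is
  a simplification — it keeps the generator's mirror symmetry exact and
  errs on the *harder* side for the inversion, since coherent energy is
  not averaged away.
* **Speech-like target**: pink-spectrum noise with 4 Hz amplitude
  modulation and brief pauses, peak 0.5 — a stand-in for a recorded
  speech sample with a comparable long-term spectrum and envelope. It
  has no harmonic structure or formants; none of the physical metrics
  here depend on those.

What passing tests on this fixture do show: the design pipeline's
conditioning, delay bookkeeping, and mismatch behavior under realistic
interaural structure, reflections and reverberant truncation. What they
do not show: performance against measured HAD transfer functions with
pinna/torso detail, device microphone responses, or measurement noise
floors — absolute separation figures on real hardware will differ.

## Metrics

With unit-impulse targets to one channel at a time, channel separation
is \(CS_1 = |p_1/p_2|\) (left impulse) and \(CS_2 = |p_2/p_1|\) (right
impulse), reported in dB on the one-sided evaluation FFT grid and capped
at 120 dB where the dark channel underflows (`channel_separation()`).
All dB values are \(20\log_{10} x\). Spectra are exact DTFT values at
the bin frequencies (alias-folded DFT of the full linear convolution),
not truncated FFTs. Time-domain accuracy uses the per-sample absolute
error \(AE_m[n] = |d_m[n] - p_m[n]|\) after alignment and a 76,800-sample
(1.6 s) crop, its mean (MAE), and a Savitzky–Golay smoothed version
(window 1001, order 1) for presentation. `response_analysis()`
summarizes bright-channel magnitude flatness (max deviation from the
band mean over 100–7800 Hz, the effective passband) and phase linearity
(max group-delay deviation from the band median — robust to the constant
shift that the inversion legitimately introduces).

The evaluation always propagates through the **raw, unwindowed** plant:
the mismatch between the windowed design plant and the full physical
plant is precisely the phenomenon under test in the booth.

`rotation_sweep()` re-simulates the plant over ±10° of head rotation in
1° steps and evaluates both modes: *uncompensated* (0° filters reused)
and *compensated* (filters redesigned per angle with identical
parameters, including the same window). At 0° the two modes coincide
exactly. On the anechoic fixture, uncompensated separation decays
monotonically with rotation while compensation restores it — the
package's robustness tests assert both properties.

## Numerical choices

* One-sided spectra everywhere; Hermitian symmetry enforced on synthesis.
* Float64 throughout; 24-bit integers exist only at WAV boundaries.
* Convolutions are FFT-based full linear convolutions, never truncated.
* Alignment is by the *known* constant delay; cross-correlation runs
  only as a diagnostic that warns on disagreement beyond ±1 sample.
* The causal shift is the deterministic centroid rule of stage 8; when
  design and evaluation share a plant, the recorded `total_delay` equals
  the end-to-end delay exactly (tested to ±1 sample).
* "Most frequencies" is operationalized as ≥90% of bins in the report
  band (a 10th-percentile statistic).
* MAE is reported linear and in dB; dB values depend on target level, so
  fixtures pin the speech-like peak at 0.5 for comparability.

## Problem sizes

The shipped configuration uses 48 kHz audio, design FFT 8192, IR lengths
of 2048 (anechoic) / 8192 (booth) samples, a 1.6 s evaluation crop and
2 s measurement sweeps in the scenario runners; the full stationary
scenario and a 21-angle rotation sweep each complete in seconds to a few
minutes on a single core. All sizes are configuration parameters.

## Known limitations

* The head model has no torso, pinna or elevation; measured transfer
  functions cannot be imported (by design — the simulator is a fixture,
  not an HRTF engine).
* Rooms are first-order image sources plus a coherent diffuse tail; no
  higher-order reflections or frequency-dependent absorption.
* Regularization is frequency-independent, as in the underlying method;
  no perceptual weighting.
* Real-time/streaming rendering and audio-device I/O are out of scope;
  convolution is offline.
* Two microphones only; extensions to more microphones per device are
  not implemented.
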