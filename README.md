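# ctcva

Two-loudspeaker crosstalk-cancellation virtual acoustics for
hearing-assistive devices.

## What this is for

Testing the spatial hearing of hearing-aid and cochlear-implant users
normally requires a large, expensive loudspeaker array in a heavily
treated room. A compact alternative: two loudspeakers and inverse filters
that control the sound pressure directly at the *device microphones*, so
the devices receive the same signals a real source anywhere in space
would produce. `ctcva` is a toolkit for building and evaluating such a
system — for audio/audiology researchers and engineers who want to
measure transfer paths, design the inverse filters, render virtual
sources, and quantify how physically accurate the reproduction is,
including under small head rotations. A plant simulator (rigid-sphere
head, anechoic and reverberant-booth presets) makes every part of the
pipeline runnable and testable without hardware.

## The method

Per frequency bin, with plant matrix `G(ω)` (M×2 microphones ×
L loudspeakers) and target microphone pressures `d(ω)`, the loudspeaker
signals are the Tikhonov-regularized pressure-matching solution

    q₀(ω) = Gᴴ(ω) (G(ω) Gᴴ(ω) + βI)⁻¹ d(ω) e^(−jωτ)

so that the reproduced pressures satisfy `p = G q₀ ≈ d·e^(−jωτ)`, with
regularization `β` stabilizing the inversion and modeling delay `τ`
buying causality. The filter design runs an eight-stage pipeline
(normalize → Tukey-window → FFT → per-bin inversion → IFFT → 99-tap
linear-phase low-pass at 8 kHz → peak-normalize → causal shift); quality
is reported as channel separation `CS₁(ω) = |p₁/p₂|` (and its mirror),
magnitude flatness, phase linearity, and per-sample absolute error after
alignment. See the methods vignette
(`vignettes/pressure-matching.Rmd`) for the full account.

## Worked example

```r
library(ctcva)

preset <- anechoic_preset()
plant  <- simulate_hadirs(head_model_spec(), preset$room, preset$layout)
va     <- subset_spks(plant, c("L1", "R1"))     # the reproduction pair
bank   <- design_filters(va, default_window(va, "anechoic"),
                         design_config(beta = 5e-4))
print(bank)
#> <inverse_filter_bank> 2 x 2 filters, 8290 taps @ 48000 Hz
#>   beta 0.0005, fft_size 8192, total_delay 4354 samples, level_comp 0.5413

cs <- channel_separation(bank, va)
print(cs)
#> <cs_curves> 4097 bins; 100-7800 Hz: min CS1 35.0 dB, min CS2 35.0 dB

resp <- response_analysis(cs)
#> flatness: 0.15 dB, group-delay deviation: 0.038 samples

speech <- speech_like_signal(1.6, seed = 1)      # 76,800-sample target
target <- make_target(plant, "L3", speech, bank$config)  # source at -90°
rep    <- reproduce(target, bank, va)
mae <- mean_absolute_error(absolute_error(rep$d, rep$p))
#> MAE (L3 target): -62.9 dB / -69.8 dB
```

Reading the numbers: channel separation never falls below 35 dB across
the 100–7800 Hz effective passband (≥20 dB is the usual threshold for
perceptually transparent binaural reproduction), the bright-channel
magnitude response deviates at most 0.15 dB from flat, group delay is
constant to a few hundredths of a sample (linear phase), and a
speech-like signal from the hard-left source L3 — 105° away from the
nearest reproduction loudspeaker — is reproduced at the microphones with
a mean absolute error 60–70 dB below full scale.

Full experiments, including the booth room-adaptation case (anechoic
targets reproduced inside a reverberant booth) and the ±10° head-rotation
sweep in compensated/uncompensated modes:

```r
run_stationary_scenario(scenario_config("booth", seed = 1, out_dir = "out"))
run_rotation_scenario(scenario_config("anechoic", seed = 1, out_dir = "out"))
```

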