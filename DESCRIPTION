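Package: ctcva
Title: Two-Loudspeaker Crosstalk-Cancellation Virtual Acoustics for
    Hearing-Assistive Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Toolkit for compact virtual-acoustics testing of
    hearing-assistive devices. Measures (or simulates) impulse responses
    between loudspeakers and behind-the-ear device microphones, designs
    Tikhonov-regularized crosstalk-cancellation inverse filters by
    pressure matching, renders virtual sound sources through a
    two-loudspeaker pair, and evaluates physical reproduction accuracy
    with channel-separation and time-domain error metrics, including
    robustness to small head rotations. Includes an exponential
    sine-sweep measurement module, a rigid-sphere plant simulator with
    anechoic and reverberant-booth presets, and end-to-end scenario
    runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
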