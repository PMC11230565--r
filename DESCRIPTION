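Package: deepscan
Type: Package
Title: Two-Stage Detection of Vessel Noise in Estuarine Passive Acoustic
    Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects burst-broadband recreational-vessel noise in calibrated
    passive-acoustic WAV recordings using a two-stage "deep scanning"
    procedure: a time-domain stage frames the waveform, computes calibrated
    broadband sound pressure levels (SPL) and gates frames against the
    file-wide median SPL, and a frequency-domain stage classifies fixed-size
    spectrogram feature windows around each candidate with a small
    feed-forward neural network.  Includes snapping-shrimp transient removal,
    sound exposure level (SEL) metrics, per-file evaluation against manual
    labels, and a synthetic estuarine soundscape simulator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, yaml, pracma
Suggests: testthat (>= 3.0.0), optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
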