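Package: rppghrv
Title: Contactless Heart Rate Variability from Facial Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A remote-photoplethysmography (rPPG) pipeline that recovers the
    cardiac pulse from facial video and compares the resulting heart rate
    variability (HRV) against a contact photoplethysmogram. The pipeline
    detects and stabilizes a facial region of interest, amplifies subtle
    pulse-synchronous colour changes with Eulerian video magnification,
    extracts the red-channel mean as a pulse signal, detects systolic peaks
    to obtain NN intervals, and computes a catalogue of 63 HRV features
    (15 time-domain, 36 frequency-domain via Welch, autoregressive Burg and
    Lomb-Scargle spectral estimators, and 12 non-linear features including
    Poincare geometry, sample entropy and detrended fluctuation analysis).
    Paired video and PPG recordings are aligned in time and compared with
    heart-rate error metrics and per-feature Pearson, Spearman and Kendall
    correlation tests under Benjamini-Hochberg false-discovery-rate control.
    A seeded synthetic-data module generates ground-truth RR series with
    band-limited autonomic modulation plus matched PPG traces and skin-patch
    videos, so every stage is testable without human recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
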