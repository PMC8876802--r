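Package: voiceinv
Title: Age-Robust Voice Individuality Analysis Across Vocal Development Periods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying voice individuality that survives age-related
    vocal change across adolescence. Provides a seeded source-filter generator
    for two-period (unstable/stable) voice corpora with controllable
    speaker-invariant resonances, linear-frequency cepstral coefficient (LFCC)
    extraction with a 60-band uniform filter bank, a small feedforward neural
    network speaker verifier (batch normalization, softmax, Adam) fitted as a
    classed model object, equal-error-rate based verification accuracy from a
    swept decision threshold, per-band Fisher F-ratio discriminability
    profiles, and a band-median centroid resampling analysis that quantifies
    which frequency regions carry period-robust individuality.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
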