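Package: csibreathe
Title: Non-Contact Breathing Monitoring from WiFi CSI Ratio Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts respiration waveforms and breathing rate from
    multi-antenna WiFi Channel State Information (CSI) by tracking the
    two-link CSI-ratio trajectory on the I/Q plane. Provides a synthetic
    CSI generator with known breathing ground truth, Gaussian-process
    interpolation of non-uniformly sampled CSI, static-path removal,
    two-link ratio computation that cancels carrier frequency offset and
    packet detection delay, dispersion-based motion-artifact rejection,
    Gaussian-basis trajectory fitting, turning-point breath-transition
    detection with signed arc-length waveform reconstruction, and
    breathing-accuracy metrics (ACC, MAE, AER).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
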