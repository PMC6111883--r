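Package: wristauth
Title: Multimodal Wrist-Band Biometric Authentication with ECG and
    Multispectral Skin Photomatrix Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a distance-based multimodal biometric
    verification pipeline for wearable wrist-band sensors.  Continuous
    single-lead ECG is band-pass corrected, R-peaks are located with a
    Pan-Tompkins detector, and aligned P-QRS-T pulses are averaged into
    enrollment records; multispectral skin photomatrix (MSP) cycles are
    aggregated into 128-dimensional light-intensity features.  Probes
    may be denoised with a user-template guided filter before
    max-normalized Euclidean-distance scoring, and the two modalities
    are fused by single-threshold majority voting (AND/OR).  A
    verification-protocol evaluator reports FAR/FRR curves, EER, the
    detection probability at 1% FAR and the false-rejection rate at
    zero FAR, and a synthetic cohort generator provides ground-truthed
    ECG signals and MSP cycle data for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
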