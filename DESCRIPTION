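Package: ratresp
Title: Camera-Based Respiration Monitoring of Unconstrained Rodents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the respiratory rate of unconstrained laboratory rats
    from video by tracking the projected area of the segmented
    thorax/abdominal region. Provides a pluggable per-frame segmenter
    contract with a reference intensity-threshold segmenter, certainty-score
    validity gating and IoU evaluation against polygon annotations,
    noise-subspace projection denoising of the area signal against
    center-of-mass motion regressors, Butterworth band-pass conditioning,
    gradient clipping, zero-crossing breath-peak detection with outlier
    rejection, an ECG-derived respiration (EDR) reference branch with
    rat-tuned R-peak detection, study-level error summaries, and a
    ground-truthed synthetic data generator (breathing elliptical blobs and
    amplitude-modulated rat ECG) so the whole pipeline is testable without
    animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
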