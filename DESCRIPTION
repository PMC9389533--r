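Package: ttroi
Title: Video-Level Diagnosis from Frame-Wise Endoscopic Classifier Output
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns per-frame lesion classifications emitted by an endoscopic
    computer-aided diagnosis model into video-level cancer diagnoses and
    evaluates them. Cancer recognition tags are merged into regions of
    interest with a gap rule, summarised as the total time of the regions of
    interest (TTROI), thresholded by ROC analysis with Youden cutoff
    selection, and scored with diagnostic-accuracy metrics (Wilson and
    log-method confidence intervals), agreement statistics (Cohen's kappa,
    McNemar) and the associated hypothesis tests. A calibrated synthetic
    generator of per-frame detection streams lets the whole pipeline run at
    desk scale without any video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    withr
Config/testthat/edition: 3
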