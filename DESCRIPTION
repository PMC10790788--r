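Package: suaseg
Title: Spatial Uncertainty Aggregation for Segmentation Heatmaps
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing of probabilistic segmentation heatmaps from deep
    ensembles, aimed at detecting false-negative (FN) regions in digital
    pathology whole-slide images. Negative-prediction regions (NPRs) are
    extracted as connected components of pixels whose fused softmax lies
    between a lower bound and the positive threshold; per-pixel predictive
    entropy is aggregated within each region (mean or 90th percentile) and
    regions whose aggregate exceeds a calibrated threshold are flagged as
    FNs and optionally converted to positive predictions. Includes a
    pixel-independent baseline, an evaluation stack (F-beta, Dice, false
    negative conversion rate, lesion-level FROC, slide-level ROC-AUC,
    slide-resampling bootstrap), a synthetic slide generator with planted
    FN structure and a domain-shift knob, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
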