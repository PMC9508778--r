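Package: gazepheno
Title: Gaze Phenotyping of Naturalistic Video Viewing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying individual gaze phenotypes from
    eye tracking of naturalistic videos. Builds per-frame areas of interest
    (faces, eyes, mouth, hands, body, non-social background) from face-box and
    facial-keypoint detections, codes raw gaze streams to those areas via a
    one-degree disk maximum-overlap rule, computes Gaussian gaze heatmaps and
    leave-one-out reference-heatmap correlations, and estimates group effect
    sizes (bootstrap Cohen's d), within-individual reliability (epoch-sampled
    Spearman correlation, partial rank correlation), gaze fingerprinting
    (nearest-neighbour identification with a permutation null), supervised
    diagnostic classification (Gaussian naive Bayes) and unsupervised subgroup
    discovery (variational Bayesian Gaussian mixtures over moving windows).
    Includes a synthetic cohort generator with stable per-participant gaze
    traits, group-level shifts, session jitter and missingness so every stage
    can be exercised and calibrated without raw eye-tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
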