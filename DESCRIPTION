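Package: e4mood
Title: Self-Supervised Mood-Episode Classification from Wrist-Worn
    Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting acute mood-disorder episodes from
    Empatica-E4-style wristband recordings. Implements the full analysis
    stack: session import/export for the per-channel CSV export dialect,
    synthetic cohort simulation with controlled wear/nonwear, sleep/wake
    and class structure, preprocessing (on/off-body detection, minimum
    wear-run enforcement, arm-angle sleep scoring, sliding-window
    segmentation, channel standardization), handcrafted feature
    extraction for classical baselines, two self-supervised pretext
    tasks (masked prediction with geometric-run masks and masked RMSE;
    transformation prediction over six signal augmentations with
    channel-average cross-entropy), a multirate channel-embedding
    transformer classifier trained with AdamW and a reduce-on-plateau
    schedule, linear-readout and fine-tuning transfer, segment- and
    subject-level (majority-vote) evaluation, and an ablation harness
    with paired-t and linear-mixed-effects model comparisons under
    Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    signal,
    pROC,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'synth.R'
    'nn-core.R'
    'e4mer.R'
    'e4mood-package.R'
    'pretext.R'
    'train.R'
    'evaluate.R'
    'preprocess.R'
    'features.R'
    'session-io.R'
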