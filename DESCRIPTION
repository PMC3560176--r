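Package: sitstill
Title: Objective Phenotyping of Adult ADHD from Motion Capture and
    Continuous Performance Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for objective case-control phenotyping of adult
    attention-deficit/hyperactivity disorder (ADHD). Extracts hyperactivity
    measures (microevents, displacement, movement area, immobility, and
    spatial/temporal scaling exponents) from infrared motion-capture marker
    trajectories, scores two continuous-performance attention tasks
    (a high-target-density cognitive control task with 30-second
    attention-state epoch classification, and a letter CPT with
    signal-detection and reaction-time regression measures), and runs the
    full discriminability comparison between activity and attention
    measures: covariate-adjusted group tests with false-discovery-rate
    control, Cohen's d with bootstrap confidence intervals, trapezoidal
    ROC-AUC with DeLong confidence intervals and paired curve comparison,
    random-forest variable importance, and a repeated split-sample
    predictive-modeling harness over six model families. A synthetic-cohort
    generator calibrated to published group summary statistics makes every
    stage testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    nnet,
    e1071,
    randomForest,
    glmnet,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
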