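Package: quartersleep
Title: Time-Resolved Polysomnography Features and Classification for
    Central Disorders of Hypersomnolence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts interpretable feature sets from overnight
    polysomnography (hypnograms, single-channel EEG and hypnodensity
    probability matrices), both whole-night and per quarter-night:
    sleep-stage proportions, total sleep time, stage shift index, REM
    sleep-onset latency, 5x5 stage-transition matrices, stage-conditional
    multitaper relative EEG band powers, and hypnodensity marginals,
    pairwise mixed-state products and entropy.  Provides a resampled,
    class-balanced classification framework (stratified 70/30 splits,
    SMOTE augmentation, correlated-feature removal, random forest /
    gradient boosting / Gaussian process backends) with removal-based
    feature importance for narcolepsy type 1 versus other hypersomnolence
    groups, per-feature age-adjusted ANOVA screening with false discovery
    rate control and Tukey pairwise comparisons, and a synthetic cohort
    generator that emulates group-dependent sleep architecture so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    xgboost,
    kernlab,
    pROC,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
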