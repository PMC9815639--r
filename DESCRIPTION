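Package: tailbitr
Title: Early Warning of Tail-Biting Outbreaks from Electronic Feeder Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pen-level early-warning analysis of tail-biting outbreaks in
    grower-finisher pigs from electronic feeder event logs. Converts per-visit
    feeder records into daily per-pig feeding-behaviour observations (visit
    frequency, feed consumption, within-day intake variability), assembles
    them into labeled sliding analysis windows around the outbreak date,
    and benchmarks seven classifiers under two train/test split regimes that
    contrast window-level resampling with pen-held-out prediction. Includes
    a synthetic multi-herd feeder-log generator with configurable pre-outbreak
    behavioural drift, confusion-matrix reporting with Cohen's kappa and
    no-information-rate tests, paired comparison of resampling profiles, and
    a window-size sensitivity sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    kernlab,
    nnet,
    class,
    tools,
    mixOmics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
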