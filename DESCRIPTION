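Package: flysleep
Title: Sleep, Courtship, and Calcium-Trace Quantification for Drosophila
    Behavioral Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for Drosophila sleep-courtship
    experiments: reading and writing Trikinetics-style activity-monitor
    (DAM) text files, scoring sleep as runs of inactivity of at least five
    minutes, bout decomposition and diurnal summaries, ethogram window
    scoring of nighttime video, courtship index and censored
    latency-to-court/copulation analysis with a log-rank test, GCaMP
    delta-F/F0 quantification with exponential photobleaching correction,
    the study-style statistical decision procedure (D'Agostino-Pearson
    normality gate, Brown-Forsythe variance gate, Welch corrections,
    interaction ANOVA with post-hoc families, dual-control screen-hit
    rule), and a two-state semi-Markov behavior simulator that emits every
    input format with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    car,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
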