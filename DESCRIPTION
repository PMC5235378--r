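Package: atmrace
Title: Activation Threshold and Horse-Race Models of Partial Response
    Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Simulation and fitting of two competing accounts of partial
    response inhibition in anticipatory response inhibition and stop-signal
    tasks: an activation threshold model, in which Gaussian facilitatory
    drive must exceed a (possibly step-elevated) inhibition level, and a
    horse-race model, in which independent go and stop processes race to a
    fixed decision threshold.  Provides closed-form curve evaluation and
    threshold-crossing onset times, Monte-Carlo simulation of motor evoked
    potential amplitudes and electromyographic onset, offset and onset-rate
    measures, a tertile-binned Pearson chi-square objective minimised by
    multi-start Nelder-Mead, small-sample corrected AIC model comparison,
    and generators for pseudo-empirical datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
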