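Package: msrecur
Title: Recurrent-Event Regression Models for Multiple Sclerosis Relapse Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing recurrent-event regression models in
    relapsing-remitting multiple sclerosis trials. Provides a lesion-based
    Weibull trial simulator, counting-process data layouts for six extended
    Cox formulations (time-to-first-event, Andersen-Gill, PWP total-time and
    gap-time, WLW marginal, LWA common-baseline), a stratified Cox
    partial-likelihood fitter with cluster-robust sandwich variance and
    martingale residuals, Poisson and GEE-Poisson person-time count models,
    a Monte-Carlo bias/MSE study orchestrator, and an end-to-end applied
    analysis pipeline for long-format recurrent-event trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
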