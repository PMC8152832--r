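Package: inhibmet
Title: Stop-Signal Inhibition Measures and Tissue-Corrected MRS Neurometabolite Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline linking stop-signal task inhibition
    measures to proton magnetic resonance spectroscopy (1H-MRS) neurometabolite
    levels. Provides an independent race-model simulator for the anticipated-response
    stop-signal task with one-up-one-down staircase tracking of the stop-signal
    delay, integration-method estimation of the stop-signal reaction time (SSRT)
    and proactive-slowing measures, partial-volume and relaxation correction of
    water-referenced metabolite signals with quality-control gating, and the
    statistical chain used in aging studies of inhibitory control: pooled t-tests
    with Benjamini-Hochberg false discovery rate control, Pearson correlation
    screening, multiple regression with R-squared-change variance partitioning,
    and Fisher r-to-z comparison of correlations between groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
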