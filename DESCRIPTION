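Package: granulayer
Title: Simulation of Recoding in the Cerebellar Granular Layer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded, testable simulator of recoding in the granular layer of
    the cerebellar cortex. Computes expected and realized numbers of granule
    cells crossing a fixed input threshold under a glomerular Golgi-cell veto
    (a binomial population model), runs the homeostatic regulation of
    parallel-fiber activity over beams of mossy-fiber cluster fields by
    damped fixed-point iteration of the Golgi feedback loop, reproduces the
    central-limit-theorem recoding of mossy-fiber firing rates into
    granule-cell sample means with top-slice selection, and derives the
    binomial overlap spectrum of stored parallel-fiber patterns. All
    experiments are driven by a JSON configuration, emit tidy tibbles and CSV
    tables with a JSON provenance sidecar, and are byte-reproducible under a
    fixed seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
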