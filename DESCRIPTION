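Package: nestrec
Title: Incubation Recess Detection and Analysis from Nest Temperature Loggers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying shorebird incubation behaviour from 1-minute
    nest thermologger traces. Detects incubation recesses with a daily
    maximum-drop threshold rule, separates short from extended recesses at the
    antimode of the bimodal recess-duration distribution (kernel density on the
    log scale, with a bootstrap confidence interval), builds pre-recess
    ground-temperature and body-condition (scaled mass index) covariates, and
    fits mixed-effects occurrence, duration and total-daily-recess models with
    AIC time-window optimization, Nakagawa R-squared, and simple-slopes /
    Johnson-Neyman interaction probing with false-discovery-rate control. A
    synthetic-study generator with known behavioural ground truth supports
    end-to-end validation without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
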