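Package: hcmtwitch
Title: In-Silico Cardiomyocyte Twitch Modelling of Hypertrophic Cardiomyopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates calcium-driven active-tension twitches of human
    cardiomyocytes with an explicit myosin DRX:SRX availability parameter and
    a myosin-to-thin-filament feedback on calcium sensitivity. Provides
    genotype-specific sarcomere remodelling for the hypertrophic
    cardiomyopathy variants MYH7 R403Q, TNNT2 R92Q and TNNI3 R21C,
    populations of models built by Latin hypercube sampling and biomarker
    calibration, absolute-sensitivity analysis, and in-silico drug trials
    (Mavacamten dose-response, calcium/late-sodium current block, SERCA
    upregulation, and a thin-filament calcium desensitiser), together with
    twitch and calcium-transient biomarker extraction and nonparametric
    population statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    generics,
    deSolve,
    dplyr,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
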