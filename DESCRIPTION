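Package: emodeb
Title: Engagement-Related Behavior Coding, Reliability and Path Modelling
    for Dementia Dyads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the ELICSE behavioral coding scheme and the EMODEB
    evidence-based model of engagement-related behavior in people with
    dementia. Reads and validates time-stamped annotation event logs over
    three mutually exclusive body-part behavior groups (head, torso,
    arms/hands) with affect modifiers; computes two-coder inter-rater
    reliability as Cohen's kappa with a temporal tolerance window; reduces
    streams to per-session duration percentages and the six EMODEB
    engagement scores; classifies instant-by-instant engagement levels,
    affect intensity and Laban body-part-organization patterns; and fits
    the fixed 9-path recursive structural model by maximum likelihood with
    standard errors, chi-square and incremental fit indices, after
    Mahalanobis outlier screening. A synthetic-data module simulates
    paper-sized dyadic session cohorts and a two-coder noise model so the
    whole pipeline is testable without video data.
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
    purrr,
    readr,
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
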