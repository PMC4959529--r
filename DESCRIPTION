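Package: gazegames
Title: Process-Tracing Analysis of Eye Movements in 2x2 Strategic Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying the cognitive process of choice in symmetric
    2x2 games from eye-movement records. Builds a payoff-difference game
    space (prisoner's dilemma, stag hunt, hawk-dove and dominance-solvable
    games); computes level-k choice predictions, simulates the lookup
    sequences the theory implies, and fits mixtures of reasoning levels by
    maximum likelihood; simulates choices and fixation streams from a
    gaze-coupled drift-diffusion model; assigns fixations to payoff areas of
    interest, undoes counterbalancing into a canonical frame, and classifies
    transitions into a common/rare taxonomy; fits a saturated log-linear
    model of transition frequencies; fits logistic choice-from-gaze models
    with nesting-corrected BIC and Nagelkerke R-squared; and generates
    synthetic cohorts so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
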