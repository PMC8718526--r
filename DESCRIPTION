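Package: mptcoop
Title: Multinomial Processing Tree Analysis of Cooperation and Costly
    Punishment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models cooperation and costly punishment in a simultaneous
    one-shot Prisoner's Dilemma game with a multinomial processing tree
    (MPT): a cooperation probability C, conditional probabilities of
    moral, hypocritical and antisocial punishment, and an unspecific
    punishment bias b. Provides a generic MPT engine (EQN model files,
    category probabilities, multinomial likelihood, G-squared),
    maximum-likelihood fitting over multiple groups with equality
    constraints, standard errors from the observed information, local
    identifiability checks, nested likelihood-ratio tests with Cohen's w
    effect sizes, noncentral chi-square power and sensitivity analysis,
    and a fully synthetic game simulator (payoffs, punishment heights,
    training trials, tone-task exclusions) so the complete analysis
    pipeline runs and is testable without any behavioral data.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
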