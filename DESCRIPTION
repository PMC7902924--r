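Package: ilsRL
Title: Reinforcement-Learning Models of Mitigation Investment Decisions in a
    Landslide Microworld
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an interactive landslide-mitigation microworld in which
    agents repeatedly decide what fraction of their income to invest against
    landslide risk, and models those decisions with five reinforcement-learning
    decision models (expectancy-valence, prospect-valence learning, their
    hybrids, and a random baseline) acting over ten investment-ratio bins.
    Model parameters are calibrated to cohort mean investment trajectories by
    a real-coded genetic algorithm minimising squared deviation plus one minus
    R-squared, and models are compared by OLS formulations of the Akaike
    Information Criterion, including generalization of frozen parameters to a
    held-out damage condition. Includes a synthetic-cohort generator emulating
    the qualitative structure of human investment trajectories for end-to-end
    testing and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
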