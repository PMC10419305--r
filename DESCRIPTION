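Package: obesnet
Title: Hybrid Social-Network and System-Dynamics Simulation of Obesity Spread
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the spread of obesity through an emergent dynamic social
    network. An agent-based component grows and maintains a contact network from
    propinquity, BMI homophily, interaction memory and a per-slot acceptance
    capacity; a per-agent Theory-of-Planned-Behaviour stock-flow component turns
    neighbourhood norms, attitudes and perceived behavioural control into dieting
    decisions; and an energy-balance engine converts calorie intake and
    expenditure into monthly weight change. Includes a synthetic population
    generator, a scenario engine with a network-off counterfactual, network
    topography metrics, and SPSA (simultaneous perturbation stochastic
    approximation) calibration of the model parameters against mean/median BMI
    reference series.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
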