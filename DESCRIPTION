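Package: peopt
Title: Metaheuristic Optimization of School Physical Education Schedules
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing weekly school physical-education (PE) schedules
    that maximize a weighted multi-metric health fitness score over a student
    cohort. Provides a seeded synthetic cohort generator with controllable
    missingness and outlier injection, a preprocessing chain (mean/mode
    imputation, Tukey/IQR outlier removal, min-max scaling, one-hot encoding),
    an energy-balance health response model built on MET-based caloric
    expenditure and a Mifflin-style basal metabolic rate, six from-scratch
    metaheuristics (genetic algorithm, particle swarm, ant colony, simulated
    annealing, differential evolution, artificial bee colony) over a mixed
    continuous/integer/simplex decision space with an exhaustive-search test
    oracle, and experiment drivers for convergence comparison, replicate
    summaries with confidence intervals, and fitness-weight sensitivity
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
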