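Package: mtforage
Title: Multi-Timescale Reward Integration and Matching Behavior in Dynamic Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for dynamic foraging experiments under
    concurrent variable-interval (baiting) reward schedules. Provides a trial-level
    task simulator with changeover delay, choice models that integrate reward
    history over multiple exponential timescales, model-independent behavioral
    statistics (block-wise matching regression, undermatching, color choice bias,
    harvesting efficiency, variance of choice), exact bias-variance moment
    recursions for leaky-integrator value estimation, per-session maximum
    likelihood fitting of integrator weights with slow-income carryover, the
    longest measurable integration timescale (LMIT) statistic with a conservative
    block permutation test, and a metaplastic (cascade) synapse decision model
    with inter-session forgetting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
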