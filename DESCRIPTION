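Package: pixssm
Title: Synthetic Somatic Marker Agents in a Stochastic Binary Grid-World
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a stochastic binary grid-world (the "Pixelverse") in
    which an agent accumulates a scalar valence over compressed state
    signatures and uses a threshold rule to decide whether to keep the
    current trajectory or reset the environment -- a minimal computational
    analogue of the somatic marker hypothesis. Provides the environment
    (Bernoulli grids, per-cell stochastic flips, row-count signature
    compression, a stability oracle), the valence memory with clipped
    incremental updates, three baseline agents (calibrated random policy,
    empirical good-frequency rule, tabular Q-learning over signatures), a
    seeded run/experiment protocol with CSV/JSON step logs, repeated-run
    summary metrics, a parameter-sensitivity sweep, and failure-mode
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
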