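Package: domhier
Title: Dominance Hierarchy Inference from Agonistic Interaction Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for inferring dominance hierarchies in group-housed
    animals from time-stamped agonistic interaction logs. Implements the
    I&SI rank-order method (minimizing inconsistencies and their strength
    in a binary dominance matrix), sequential Elo ratings, and Glicko
    ratings with rating deviations updated in hourly rating periods.
    Includes fight-validity filtering and same-pair fight merging, win/loss
    sociomatrix construction, time-to-social-stability analyses on hourly
    rating trajectories, a statistical panel (index inter-correlations,
    partial correlations, multiple regression, sex contrasts on stability
    time), and a synthetic-herd generator with a latent logistic win model
    for validation of the whole pipeline.
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
    withr,
    emmeans
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
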