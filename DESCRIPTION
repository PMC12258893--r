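Package: rnaimem
Title: Half-Life Analysis of Transgenerational RNAi Silencing Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multigenerational RNA-interference silencing-memory
    assays in Caenorhabditis elegans. Converts per-generation OFF/DIM/ON
    scoring counts into percent-GFP-positive trajectories, estimates the
    half-life of silencing memory (the interpolated 50% crossing) on a
    generation or day axis with support for larval-arrest and dauer
    schedules, compares strains and environments with Gamma log-link mixed
    models, Wald term tests and single-step (Tukey) adjusted pairwise
    contrasts, and validates fits with simulation-based randomized quantile
    residuals. Includes a synthetic-experiment generator with block and
    replicate random effects so every stage of the pipeline is testable
    without laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    glmmTMB,
    jsonlite,
    mvtnorm,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    emmeans,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
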