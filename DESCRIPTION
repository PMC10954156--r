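Package: latticetumor
Title: On-Lattice Agent-Based Tumor Growth and Model Design-Choice Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of tumor growth on hexagonal and
    rectangular lattices in two and three dimensions, with finite-difference
    or pseudo-steady-state nutrient diffusion, constant, pulse, and cyclic
    glucose sources, and configurable initial cell-to-cell variability.
    Provides emergent-behavior metrics (colony growth rate, symmetry, and
    cell cycle length), factorial experiment presets crossing geometry,
    dimension, variability, and nutrient dynamics, and a two-way ANOVA
    decision pipeline (interaction test, simple main effects with Bonferroni
    correction, and pairwise Tukey comparisons) for quantifying how model
    design choices alter emergent dynamics.
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
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
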