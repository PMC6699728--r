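Package: underdrive
Title: Deterministic Modelling of Two-Locus Engineered Underdominance Gene Drives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discrete-generation, deterministic population-genetics
    simulator for two-locus engineered underdominance (UD) gene drives in
    randomly mating populations. Each transgenic construct carries a lethal
    effector, a suppressor of the opposite construct's lethal, and a cargo
    gene; loss-of-function mutation degrades each component at a constant
    per-gene rate. The package enumerates the 18-allele / 2025-genotype
    state space, iterates the exact mating-mutation-selection recursion,
    schedules releases (including wild-type and free-suppressor reversal
    releases), locates equilibria of the mutation-free reduced haplotype
    models and classifies their stability numerically, and provides
    scenario drivers for mutation sweeps and reversal-threshold bisection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
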