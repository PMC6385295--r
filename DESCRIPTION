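Package: allofoot
Title: Structural and Functional Analysis of Anti-HLA Alloantibody Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing how a human alloantibody engages a class-I
    human leukocyte antigen (HLA). Quantifies the antibody epitope footprint on
    a Fab-HLA complex (Shrake-Rupley solvent-accessible surface area, buried
    surface area decomposed by chain pair, residue contacts and hydrogen bonds,
    discontinuous epitope segments, binding-induced backbone displacement),
    rationalizes and predicts per-allele reactivity from epitope-position
    substitutions against single-antigen-bead fluorescence panels, models
    receptor co-engagement by rigid superposition and steric-clash detection,
    simulates and fits 1:1 Langmuir single-cycle binding kinetics, and computes
    cytotoxicity percentages with exact nonparametric statistics. Includes
    seed-deterministic synthetic generators for every input class so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
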