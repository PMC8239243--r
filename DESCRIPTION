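Package: coordkit
Title: Characterization Arithmetic for Metal-Drug Coordination Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream characterization arithmetic for spectroscopic,
    thermal and biological studies of transition-metal drug complexes.
    Provides molecular-formula parsing with elemental percent composition
    and thermogravimetric mass ledgers; molar-ratio stoichiometry and
    spectrophotometric stability constants for ML2 equilibria; Wolfe-Shimer
    DNA-binding fits with Gibbs free energy and chromism; ligand-field
    (Dq, Racah B, nephelauxetic beta) and EPR g-factor analysis;
    Coats-Redfern and Horowitz-Metzger decomposition kinetics with
    activation thermodynamics; conceptual-DFT reactivity descriptors from
    frontier-orbital energies; MTT survival fractions with IC50
    interpolation and potency classification; and seeded synthetic-data
    generators with known ground truth for every input the workflow
    consumes.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
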