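Package: ramtool
Title: Build, Exchange, and Solve Metabolic Resource Allocation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for dynamic enzyme-cost flux balance analysis (deFBA) and
    resource balance analysis (RBA) of metabolic networks. Provides an in-memory
    representation of resource-allocation models (species partitioned into
    extracellular nutrients, quasi-steady-state metabolites, storage, and
    macromolecules; reactions annotated with turnover rates and maintenance
    coefficients), assembly of the enzyme-capacity, biomass-composition and
    maintenance constraint matrices, a builder protocol that derives protein
    synthesis reactions and quota compounds from amino-acid sequences, subunit
    stoichiometries and biomass-reaction coefficients, turnover-rate aggregation
    from database observations, a reader/writer/validator for the resource
    allocation modeling (RAM) SBML annotation dialect (SBML Level 3 with the
    flux-balance-constraints package), and solvers: collocation discretization
    of the deFBA dynamic optimization into a linear program, and a bisection
    solver for the RBA balanced-growth problem used to initialize simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
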