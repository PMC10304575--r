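Package: larvaflux
Title: Constraint-Based Resource-Allocation Modeling of Black Soldier Fly Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based metabolic analysis of Hermetia illucens
    (black soldier fly) larvae and similar insect systems. Provides stoichiometric
    model containers with SBML (Level 3 + FBC), COBRA JSON and tabular
    readers/writers; construction of a biomass objective reaction from
    macromolecular, fatty-acid and amino-acid composition assays; conversion of
    fed-diet descriptions into per-larva-per-day exchange bounds; flux balance
    analysis (FBA) and flux variability analysis (FVA) on a built-in
    bounded-variable simplex solver; model quality-control statistics (dead-end
    metabolites, blocked reactions, elemental balance, exchange reactions); a
    dietary carbon-conversion-efficiency statistic per fatty-acid product; a
    deterministic generator of small larva-like metabolic networks with known
    analytic optima; and a configuration-driven experiment pipeline for dietary
    perturbation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
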