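Package: anisofit
Title: Stereochemical Elucidation from Anisotropic NMR Data over Conformer Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining the relative configuration of small
    organic molecules from anisotropic NMR observables. Fits a single
    alignment (Saupe) tensor to residual dipolar couplings (RDCs) and
    referenced residual chemical shift anisotropies (Delta-Delta-RCSAs)
    over Boltzmann- or shift-selected conformational ensembles, ranks
    candidate diastereomers by Q factor, converts quantum-chemical
    conformer energies to Boltzmann populations, and performs
    Akaike-based selection of conformer populations from experimental
    1H/13C chemical shifts (CASE-3D style). A fully seeded synthetic-data
    generator produces ground-truthed conformer ensembles, shielding
    tensors, and noisy RDC/RCSA/shift tables, including inverted-
    stereocenter decoy configurations, so the whole pipeline is testable
    without quantum-chemistry inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
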