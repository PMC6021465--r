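Package: nadescreen
Title: Dissociation-Aware Screening of Natural Deep Eutectic Solvents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens binary acid/amino-acid natural deep eutectic solvents
    (NADES) for solubilization of poorly water-soluble solutes such as the
    flavonoid rutin. Solves the coupled proton-transfer speciation
    equilibria of each solvent pair from reaction free energies or
    equilibrium constants, mixes sigma profiles of the resulting neutral
    and ionic forms by their equilibrium mole fractions, computes
    infinite-dilution activity coefficients from the self-consistent
    segment chemical-potential equations of conductor-like screening
    (COSMO-RS) theory, calibrates the computed ln gamma against
    experimental solubilities by ordinary least squares, and ranks
    candidate solvent pairs by predicted solubility. Includes seedable
    synthetic-fixture generators (sigma profiles, reaction networks with
    known equilibria, training sets with known truth) so the entire
    pipeline runs without external quantum-chemistry software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
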