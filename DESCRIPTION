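Package: dimerscope
Title: Dimerization Analysis of Coarse-Grained Membrane-Receptor Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for large ensembles of coarse-grained
    self-assembly simulations of membrane receptors such as G protein
    coupled chemokine receptors. Detects dimerization and dissociation
    events from interaction-energy time series with a two-threshold
    criterion, estimates first-order association rates and lower-bound
    binding free energies, classifies dimer interfaces from relative
    orientation angles via periodic kernel density height-fields and
    watershed segmentation, computes per-helix binding-position densities,
    residue-resolved cholesterol occupancies and spatial densities,
    lateral diffusion coefficients, structure metrics (superposed RMSD,
    buried surface area, percent identity) and distance-decayed elastic
    network bonds. A synthetic-data module generates miniature ensembles
    with known ground truth so the whole pipeline is testable without
    molecular dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage
Suggests:
    bio3d,
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
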