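Package: hjbind
Title: Ion Binding and Folding Analysis for DNA Four-Way Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of metal-ion binding to DNA four-way
    (Holliday) junctions. Computes FRET efficiencies from acceptor emission
    spectra by the (ratio)A method, Forster radii from spectral overlap
    integrals, inter-dye distances and interduplex angles; fits ion-titration
    folding curves to a two-state Hill isotherm to extract apparent binding
    affinities; forward-models and fits isothermal titration calorimetry
    thermograms with two independent classes of binding sites constrained by
    van't Hoff parameters from temperature-dependent FRET; and analyses
    lanthanide luminescence decays for hydration numbers and inter-ion
    distances by luminescence resonance energy transfer. Includes seeded
    synthetic-data generators emulating each experiment so the full pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
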