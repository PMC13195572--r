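Package: gapmerTDN
Title: Cleavage, Thermodynamics and Catalytic-Cycle Simulation for
    Gapmer-Bearing DNA Tetrahedra
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the mechanism of an RNase H-responsive tetrahedral DNA
    nanostructure (TDN) carrying an integrated anti-miRNA gapmer. Provides
    chemically annotated strand and duplex classes (DNA, RNA, LNA, 2'-O-methyl
    sugars; phosphorothioate linkages), a constraint-checked synthetic design
    generator, rule-based prediction of RNase H-competent cleavage sites and
    fragment accounting, nearest-neighbor hybridization free energies with
    per-modification increments, base-pair-resolution free-energy landscapes
    for toehold fraying and toehold-mediated strand displacement with exact
    Boltzmann occupancies, Metropolis Monte Carlo and umbrella sampling with
    multi-histogram reweighting verified against exact enumeration, and a
    stochastic (Gillespie) plus mean-field (ODE) simulator of the catalytic
    target-cleavage cycle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    deSolve,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, StructuralPrediction, Thermodynamics
RoxygenNote: 7.3.3
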