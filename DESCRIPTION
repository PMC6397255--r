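Package: dhtsim
Title: Chain-Growth Copolymerization of DNA Hairpin Tiles: Simulation and
    Single-Molecule Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the isothermal, initiator-triggered chain-growth
    copolymerization of DNA hairpin tiles (DHTs) into nanofilaments. Provides
    a strand/domain-level representation of DHT monomers with design-rule
    validation and a replay of the toehold-mediated strand-displacement
    activation cascade; a stochastic simulator of living chain-growth
    copolymerization (with a thermal step-growth control and stepwise monomer
    re-feeding); dispersity statistics (number- and weight-averaged lengths,
    sigma, PDI) and (zero-truncated) Poisson fitting of label-count
    histograms; synthesis and automatic step counting of single-molecule
    photobleaching traces; and a discretized elastic-rod normal-mode model of
    filament thermal fluctuations (RMSF) and relative bending compliance.
    All inputs can be generated synthetically, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
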