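Package: paleoEDM
Title: Empirical Dynamic Modelling of Deep-Time Diversity Drivers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Causal analysis of Phanerozoic-scale palaeobiological time
    series. Partitions the global organic-carbon burial rate into marine
    and terrestrial components from the sedimentary C/S ratio, corrects
    sampling-standardized marine-invertebrate diversity for marine food
    supply, and tests cause-effect hypotheses between the corrected
    diversity and geodynamic drivers using convergent cross mapping
    (delay embedding, simplex projection, library-size convergence) with
    phase-randomization surrogate significance testing. Includes
    false-nearest-neighbour embedding selection, seed-deterministic
    synthetic benchmark generators with known causal structure, and a
    config-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
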