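Package: reefexo
Title: Classification and Biogeochemical Characterization of Benthic Producer Exometabolomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of untargeted LC-MS/MS exometabolome
    incubation experiments contrasting dissolved organic matter released by
    benthic primary producers (corals, crustose coralline algae, fleshy
    macroalgae, turf algae) against incubated seawater controls. Implements
    the rule-based feature-classification cascade (background, transient,
    ambient, exudate, exometabolite, exudate subtypes), many-to-one Dunnett
    tests with false-discovery-rate control, carbon-weighted energetics
    (nominal oxidation state of carbon and Gibbs energy of carbon oxidation),
    abundance-weighted elemental stoichiometry, ordination and PERMANOVA of
    feature relative abundances, molecular-subnetwork enrichment and
    treatment-class congruency, bulk-biogeochemistry producer-effect tests,
    and a synthetic-experiment generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    mvtnorm
Config/testthat/edition: 3
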