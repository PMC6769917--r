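Package: faclectin
Title: Frontal Affinity Chromatography Profiling of Lectin Glycan Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitation of lectin-glycan interactions by frontal affinity
    chromatography (FAC): breakthrough-front detection on elution curves,
    dissociation-constant estimation from front retardation, Woolf-Hofstee
    calibration of column ligand content, hemagglutination-inhibition
    minimum-inhibitory-concentration logic with censored results, glycan-panel
    affinity profiling, and classification of mannose-binding jacalin-related
    lectins into specificity groups. Includes a seeded synthetic-data
    generator emulating the instrument (sigmoid breakthrough fronts with
    fluorescence noise, concentration-dependence calibration series, two-fold
    dilution plates, and lectin binding archetypes) so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
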