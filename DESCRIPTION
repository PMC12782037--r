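Package: megamorph
Title: Multimodal Specimen Identification and Biomass Estimation from
    Images and DNA Megabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining single-specimen DNA megabarcoding with
    semi-automated imaging to estimate species identity, abundance and
    per-specimen dry biomass of freshwater macroinvertebrates. Provides a
    synthetic-data generator emulating a two-camera specimen imaging
    device and per-specimen OTU read tables; morphometric feature
    extraction (area, perimeter, maximum Feret diameter) with documented
    pixel conventions; dominant-OTU taxonomic assignment with read-count
    and order-consistency filtering; dataset curation and stratified
    grouped cross-validation splits; allometric ordinary-least-squares
    baselines; a lightweight convolutional network engine for taxonomic
    classification and biomass regression with optional taxonomic
    pre-training (frozen or unfrozen base); and jackknife fold-combined
    classification and regression metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    grDevices,
    tools,
    png,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
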