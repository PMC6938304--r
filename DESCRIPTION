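Package: smartarid
Title: Standardised Marine Taxon Reference Image Catalogues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building, validating, merging and publishing
    standardised morphospecies reference image catalogues for image-based
    benthic ecology. Implements the two-table transfer format (an OTU table
    and an image table) used to exchange catalogues between research groups,
    with offline taxonomic (WoRMS-style AphiaID/LSID) and gazetteer
    (Marine Regions-style MRGID) reference stores for field autopopulation,
    conformance validation with machine-readable issues, catalogue merging
    with identification provenance, and export of the end products such
    catalogues exist to enable: Darwin Core Archives, annotation-scheme
    taxonomic trees for image annotation software, and printable HTML field
    guides. A deterministic synthetic-catalogue generator makes every
    component testable without network access or real imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
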