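Package: dwca
Title: Darwin Core Archive Publishing Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A library and command-line toolkit for the Darwin Core Archive
    publishing lifecycle: mapping local tabular data to Darwin Core terms,
    packaging and reading star-schema archives (core plus extensions,
    meta.xml structural descriptor, EML dataset metadata), validating
    record identifiers and archive integrity, managing published versions
    and publication schedules, and exporting dataset metadata as a data
    paper manuscript draft.  Bundles the Occurrence Core, Taxon Core and
    Simple Multimedia schema definitions together with a demonstration
    country vocabulary, and ships a seeded fixture generator so the whole
    pipeline is testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    yaml,
    jsonlite,
    utils,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
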