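Package: archeform
Title: Plug-and-Play Integration of openEHR Archetypes into Legacy EHR Forms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses a defined subset of the Archetype Definition Language
    (ADL 1.4), augments archetypes with the implicit mandatory constraints of
    a declarative openEHR Reference Model subset ("comprehensive archetypes"),
    generates generic legacy-EHR entry forms (pages, text objects, entry
    fields, tables) together with a component-to-archetype-path mapping table,
    records documents against the generated forms, and exports them as
    archetype-compliant XML EHR extracts wrapped in a generic extract
    envelope. Detects archetype structures the form model cannot represent,
    most importantly nested repeating nodes. Includes a seeded synthetic
    archetype generator for testing every pipeline stage without external
    archetype downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
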