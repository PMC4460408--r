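Package: procamd
Title: Process and Analysis Metadata for Computational Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for documenting computational analysis pipelines with a
    two-part metadata scheme: abstract, versioned Process documents (XML)
    describing an analysis type, and per-run Analysis Metadata (AMD)
    key-value files recording concrete executions. Provides readers and
    writers for both formats, XML schema validation, a cross-validator that
    checks an AMD against its process (file bindings, cardinalities,
    parameters, switches, reference consistency, process chaining),
    materialization of abstract command templates into executable command
    lines (glob placeholders, loop tags, binary switches), a
    version-increment comparator for process documents, a synthetic fixture
    generator with targeted corruptions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    jsonlite,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
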