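Package: dosdp
Title: Dead Simple OWL Design Patterns for Ontology Term Engineering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for authoring, validating and applying Dead Simple OWL
    Design Patterns (DOS-DPs): YAML pattern documents that template OWL class
    creation for OBO-style bio-ontologies. Parses and validates pattern
    documents (including the OBO convenience extension), parses and prints
    Manchester-syntax class expressions, renders and inverts printf templates,
    instantiates patterns into OWL classes from variable fillers (singly or in
    bulk from TSV tables), matches existing classes back to patterns to
    recover their fillers and check conformance, classifies generated classes
    with a small structural subsumption engine, derives pattern hierarchies,
    and emits markdown documentation. Reads and writes a subset of OWL 2
    functional-style syntax.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    utils,
    stats,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'context.R'
    'expressions.R'
    'template.R'
    'pattern-io.R'
    'normalize.R'
    'validate.R'
    'generate.R'
    'owl-io.R'
    'reason.R'
    'match.R'
    'docgen.R'
    'fixtures.R'
    'cli.R'
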