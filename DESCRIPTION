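Package: clamlkit
Title: ClaML Classification Parsing, OWL Export and Hierarchy Relationship Auditing
Version: 0.1.0
Authors@R: person("WHO-FIC", "Tooling", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for working with WHO family health classifications distributed
    in ClaML (Classification Markup Language). Parses ClaML documents into a typed
    in-memory classification model, exports classifications as OWL ontologies
    (RDF/XML or Turtle), supports edge-level annotation of parent-child links with
    a six-way relationship typology (Subsumption, SubProcess, Agent, Patient,
    Instrument, Complexity), tabulates relationship usage per chapter and level,
    and computes the coverage of manual mappings from classification codes to an
    upper ontology such as SUMO. Ships encodings of the published relationship
    counts and chapter list for the ICF Activities and Participation component,
    plus a deterministic synthetic-classification generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
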