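Package: nlqsparql
Title: Natural-Language Search over RDF-Annotated Biosimulation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates free-text queries into ranked SPARQL queries over the
    RDF composite annotations used in biosimulation-model repositories such as
    the Physiome Model Repository and BioModels. Query phrases are grounded to
    ontology classes (GO, OPB, FMA, ChEBI and similar) with a weighted
    similarity over preferred labels, synonyms, definitions, parent labels and
    entity descriptions, supported by an inverted Text Feature Index; an RDF
    Graph Index records which model entities each class annotates and by which
    predicate paths, so class combinations can be checked against real
    annotation patterns, compiled into SPARQL and ranked. Includes deterministic
    synthetic fixture generators, retrieval metrics (precision/recall/F,
    truncated mean average precision, area under the precision-recall curve)
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
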