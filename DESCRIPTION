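Package: ontopop
Title: Template-Based Ontology Population with Validation Sets and Pattern Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build OWL ontology content from ontology-constrained tabular
    templates. Vocabularies in OBO flat-file, Turtle or RDF/XML form are
    loaded into indexed snapshots; column range specifications (all or
    direct subclasses, optionally traversing part-of, all or direct
    individuals) are resolved into validation sets; multi-valued template
    cells are parsed and validated term by term; a pattern language in the
    style of the Ontology Pre-Processor Language (variables, defined
    variables, a createIntersection macro over bound value sets, ADD
    SubClassOf/EquivalentTo actions) is compiled, bound to template
    columns, and expanded row by row into ground axioms with minted
    identifiers for unknown terms and per-axiom provenance annotations.
    Results render as Manchester syntax frames or serialize to Turtle and
    RDF/XML. Templates round-trip through a TSV dialect and Excel
    workbooks whose hidden worksheet stores the validation term records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    readxl,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
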