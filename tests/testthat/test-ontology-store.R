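test_that("OBO loading indexes terms, labels and edges", {
  snap <- load_ontology(file.path(fixture_dir(), "mini-pato.obo"), "obo")
  iri <- pm_expand(default_prefixes(), "pato:PATO_0001407")
  expect_true(iri %in% names(snap$terms))
  expect_identical(snap$terms[[iri]]$label, "mononucleate")
  expect_identical(nrow(snap$subclass), 4L)

  empty <- load_ontology("format-version: 1.2\nontology: empty\n", "obo")
  expect_length(empty$terms, 0L)
  expect_identical(nrow(empty$subclass), 0L)
})

test_that("part-of relationships are read from OBO and OWL restriction axioms", {
  obo_path <- file.path(fixture_dir(), "mini-ma.obo")
  snap_obo <- load_ontology(obo_path, "obo")
  # text-level oracle: count relationship lines in the source directly
  n_rel <- sum(grepl("^relationship:", readLines(obo_path)))
  expect_identical(nrow(partof_edges(snap_obo)), n_rel)
  expect_identical(n_rel, 9L)

  snap_ttl <- load_ontology(file.path(fixture_dir(), "mini-ma.ttl"), "turtle")
  expect_setequal(
    paste(partof_edges(snap_obo)$part, partof_edges(snap_obo)$whole),
    paste(partof_edges(snap_ttl)$part, partof_edges(snap_ttl)$whole))
})

test_that("RDF/XML documents load, including nested restriction axioms", {
  doc <- paste0(
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"\n',
    ' xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"\n',
    ' xmlns:owl="http://www.w3.org/2002/07/owl#">\n',
    '<owl:Class rdf:about="http://ex.org/v#X"><rdfs:label>thing x</rdfs:label>',
    '<rdfs:subClassOf rdf:resource="http://ex.org/v#Y"/></owl:Class>\n',
    '<owl:Class rdf:about="http://ex.org/v#Y"><rdfs:subClassOf>',
    '<owl:Restriction>',
    '<owl:onProperty rdf:resource="http://purl.org/obo/owl/ro#part_of"/>',
    '<owl:someValuesFrom rdf:resource="http://ex.org/v#Z"/>',
    '</owl:Restriction></rdfs:subClassOf></owl:Class>\n',
    '<owl:Class rdf:about="http://ex.org/v#Z"/>\n',
    "</rdf:RDF>")
  snap <- load_ontology(doc, "rdfxml")
  expect_length(snap$terms, 3L)
  expect_identical(snap$terms[["http://ex.org/v#X"]]$label, "thing x")
  expect_identical(nrow(snap$subclass), 1L)
  po <- partof_edges(snap)
  expect_identical(po$part, "http://ex.org/v#Y")
  expect_identical(po$whole, "http://ex.org/v#Z")
})

test_that("parse and dialect failures raise informative errors", {
  expect_error(load_ontology("[Term]\nid pato:X\n", "obo"), "malformed line")
  expect_error(load_ontology("@prefix broken", "turtle"), "turtle")
  expect_error(load_ontology("not xml at all", "rdfxml"), "rdfxml")
  expect_error(load_ontology("x", "json"), "unknown dialect")
})

test_that("range resolution reproduces the nucleation validation set", {
  ctx <- fixture_ctx("nucleation")
  snap <- ctx$snapshot
  vs <- resolve_range(range_spec("pato:PATO_0001404", "all-subclasses"), snap)
  expect_setequal(vapply(vs$members, label_or_fragment, ""),
                  c("anucleate", "binucleate", "mononucleate", "multinucleate"))
  # root itself is excluded
  expect_false(pm_expand(snap$pm, "pato:PATO_0001404") %in% member_iris(vs))
  # leaf has no children
  leaf <- resolve_range(range_spec("pato:PATO_0001407", "direct-subclasses"), snap)
  expect_length(leaf$members, 0L)
  expect_error(resolve_range(range_spec("pato:PATO_9999999", "all-subclasses"),
                             snap),
               "unknown term")
})

test_that("individual selectors work over instance edges", {
  doc <- paste0(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .\n",
    "@prefix ex: <http://ex.org/v#> .\n",
    "ex:Animal a owl:Class .\n",
    "ex:Dog a owl:Class ; ",
    "<http://www.w3.org/2000/01/rdf-schema#subClassOf> ex:Animal .\n",
    "ex:rex a owl:NamedIndividual , ex:Dog .\n",
    "ex:generic a owl:NamedIndividual , ex:Animal .\n")
  snap <- load_ontology(doc, "turtle")
  all_ind <- resolve_range(range_spec("http://ex.org/v#Animal", "all-individuals"),
                           snap)
  expect_setequal(member_iris(all_ind),
                  c("http://ex.org/v#rex", "http://ex.org/v#generic"))
  dir_ind <- resolve_range(range_spec("http://ex.org/v#Animal",
                                      "direct-individuals"), snap)
  expect_identical(member_iris(dir_ind), "http://ex.org/v#generic")
})

test_that("closures agree with an independent reachability oracle on random DAGs", {
  for (seed in 1:5) {
    snap <- random_dag_snapshot(n = 50L, seed = seed)
    root <- names(snap$terms)[1]
    for (rels in list("subclass", c("subclass", "part-of"))) {
      vs <- resolve_range(range_spec(root, "all-subclasses",
                                     traversal_relations = rels), snap)
      expect_setequal(member_iris(vs), oracle_descendants(snap, root, rels))
    }
  }
})

test_that("enlarging traversal relations never shrinks the closure", {
  snap <- random_dag_snapshot(n = 60L, seed = 11L)
  for (root in names(snap$terms)[c(1, 3, 7)]) {
    sub_only <- member_iris(resolve_range(
      range_spec(root, "all-subclasses", "subclass"), snap))
    both <- member_iris(resolve_range(
      range_spec(root, "all-subclasses", c("subclass", "part-of")), snap))
    expect_true(all(sub_only %in% both))
    direct <- member_iris(resolve_range(
      range_spec(root, "direct-subclasses"), snap))
    expect_true(all(direct %in% sub_only))
  }
})

test_that("cycles in the asserted hierarchy are tolerated with a warning", {
  doc <- paste0(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .\n",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .\n",
    "@prefix ex: <http://ex.org/v#> .\n",
    "ex:A a owl:Class ; rdfs:subClassOf ex:B .\n",
    "ex:B a owl:Class ; rdfs:subClassOf ex:A .\n")
  snap <- load_ontology(doc, "turtle")
  expect_warning(
    vs <- resolve_range(range_spec("http://ex.org/v#A", "all-subclasses"), snap),
    "cycle")
  expect_setequal(member_iris(vs), "http://ex.org/v#B")
})

test_that("loading the same document twice yields identical snapshots", {
  p <- file.path(fixture_dir(), "mini-cto.ttl")
  s1 <- load_ontology(p, "turtle")
  s2 <- load_ontology(p, "turtle")
  expect_identical(sort(names(s1$terms)), sort(names(s2$terms)))
  expect_identical(s1$subclass, s2$subclass)
})

test_that("CURIEs round-trip through the prefix map", {
  pm <- default_prefixes()
  for (curie in c("pato:PATO_0001407", "cell:CL_0000000", "MA:MA_0002546",
                  "ro:part_of", "hasNucleation")) {
    iri <- pm_expand(pm, curie)
    expect_identical(pm_contract(pm, iri), curie)
    expect_identical(pm_expand(pm, pm_contract(pm, iri)), iri)
  }
  expect_true(is.na(pm_expand(pm, "nosuch:X")))
  expect_error(prefix_map(bad = ""), "empty namespace")
})

test_that("display text falls back from label to IRI fragment", {
  expect_identical(
    label_or_fragment(term_ref("http://x#PATO_0001407", label = "mononucleate")),
    "mononucleate")
  expect_identical(label_or_fragment(term_ref("http://x#CL_0000113")),
                   "CL_0000113")
  expect_identical(label_or_fragment(term_ref("http://x/GO_0003093")),
                   "GO_0003093")
})

test_that("label search is case- and whitespace-insensitive and reflexive", {
  ctx <- fixture_ctx("nucleation")
  vs <- ctx$validations$B
  hit <- find_by_label("mononucleate", vs)
  expect_length(hit, 1L)
  expect_identical(hit[[1]]$curie, "pato:PATO_0001407")
  expect_length(find_by_label("  MONONUCLEATE ", vs), 1L)
  expect_length(find_by_label("proximal tubule epithelial cell", vs), 0L)
  for (m in vs$members)
    expect_true(m$iri %in% vapply(find_by_label(label_or_fragment(m), vs),
                                  `[[`, "", "iri"))
})
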