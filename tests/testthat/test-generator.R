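test_that("row binding collects ordered terms per mapped variable", {
  ctx <- fixture_ctx("kup")
  tpl <- fixture_template("kup_template.tsv", ctx)
  b <- bind_row(tpl, 13L, ctx$column_map)
  expect_identical(lengths(b),
                   c("?cell" = 1L, "?anatomyPart" = 1L, "?participant" = 3L))
  expect_identical(b[["?anatomyPart"]][[1]]$curie, "MA:MA_0002546")
  expect_identical(vapply(b[["?participant"]], `[[`, "", "curie"),
                   paste0("gene_ontology:", c("GO_0003093", "GO_0003098",
                                              "GO_0003106")))
  # binding equals the row's resolved tokens, looked up directly
  for (v in names(ctx$column_map)) {
    toks <- tpl$rows[[13]][[ctx$column_map[[v]]]]$tokens
    resolved <- Filter(function(t) t$status == "resolved", toks)
    got <- Filter(function(t) !ontopop:::is_placeholder(t), b[[v]])
    expect_identical(vapply(got, `[[`, "", "iri"),
                     vapply(resolved, function(t) t$term$iri, ""))
  }
  expect_error(bind_row(tpl, 1L, c("?cell" = "Z")), "not in the template")
})

test_that("an all-empty row binds to empty value lists", {
  ctx <- fixture_ctx("kup")
  cols <- lapply(names(ctx$validations), function(cn)
    column_def(cn, validation = ctx$validations[[cn]]))
  tpl <- template(cols, rows = list(c(A = "", C = "", D = "")))
  b <- bind_row(tpl, 1L, ctx$column_map)
  expect_identical(lengths(b), c("?cell" = 0L, "?anatomyPart" = 0L,
                                 "?participant" = 0L))
})

test_that("minting assigns stable zero-padded identifiers", {
  pol <- mint_policy("http://purl.org/obo/owl/kupo#", "kupo",
                     width = 7L, next_index = 1028L)
  b <- list("?cell" = list(ontopop:::placeholder_term("Juxtaglomerular complex cell")))
  b2 <- mint_unknown(b, pol)
  expect_identical(b2[["?cell"]][[1]]$curie, "kupo:KUPO_0001028")
  expect_true(b2[["?cell"]][[1]]$is_minted)
  expect_identical(b2[["?cell"]][[1]]$label, "Juxtaglomerular complex cell")

  # a binding with no placeholders passes through unchanged
  known <- list("?cell" = list(term_ref("http://x#A", label = "a")))
  expect_identical(mint_unknown(known, pol), known)

  # the same label in a later row reuses the minted identifier
  again <- mint_unknown(
    list("?cell" = list(ontopop:::placeholder_term("juxtaglomerular  COMPLEX cell"))),
    pol)
  expect_identical(again[["?cell"]][[1]]$iri, b2[["?cell"]][[1]]$iri)
  expect_identical(pol$env$next_index, 1029L)

  # distinct labels get distinct identifiers
  other <- mint_unknown(
    list("?cell" = list(ontopop:::placeholder_term("some other cell"))), pol)
  expect_false(identical(other[["?cell"]][[1]]$iri, b2[["?cell"]][[1]]$iri))
})

test_that("minting skips reserved identifiers and reports exhaustion", {
  pol <- mint_policy("http://x#", "new", width = 2L, next_index = 1L,
                     reserved = "http://x#NEW_01")
  t1 <- ontopop:::mint_one(pol, "first")
  expect_identical(t1$iri, "http://x#NEW_02")
  pol2 <- mint_policy("http://x#", "new", width = 1L, next_index = 9L)
  ontopop:::mint_one(pol2, "a")
  expect_error(ontopop:::mint_one(pol2, "b"), "exhausted")
})

test_that("generation tags every axiom with row-level provenance", {
  ctx <- fixture_ctx("nucleation")
  tpl <- fixture_template("nucleation_template.tsv", ctx)
  onto <- generate(tpl, ctx$scripts, ctx$column_map, ctx$policy,
                   snapshot = ctx$snapshot, timestamp = "2026-01-01T00:00:00Z")
  for (a in onto$axioms) {
    expect_s3_class(a$prov, "provenance_tag")
    expect_true(a$prov$row %in% seq_along(tpl$rows))
    expect_identical(a$prov$timestamp, "2026-01-01T00:00:00Z")
  }
  # axiom conservation: per-row report totals match the axiom list
  logical_kinds <- vapply(ontopop:::logical_axioms(onto),
                          function(a) a$prov$row, 1L)
  for (i in seq_along(tpl$rows))
    expect_identical(sum(logical_kinds == i),
                     onto$report$axioms[onto$report$row == i])
  # every minted term appears in at least one axiom
  for (m in onto$minted)
    expect_true(any(vapply(onto$axioms, function(a)
      a$axiom$subject$iri == m$term$iri, TRUE)))
})

test_that("an empty template generates a valid but axiom-free ontology", {
  ctx <- fixture_ctx("nucleation")
  cols <- lapply(names(ctx$validations), function(cn)
    column_def(cn, validation = ctx$validations[[cn]]))
  tpl <- template(cols, rows = list())
  onto <- generate(tpl, ctx$scripts, ctx$column_map, ctx$policy,
                   snapshot = ctx$snapshot)
  expect_length(onto$axioms, 0L)
  txt <- render_manchester(onto)
  expect_match(txt, "Ontology: <")
  expect_false(grepl("Class:", txt))
})

test_that("identical inputs render byte-identical Manchester output", {
  ctx <- fixture_ctx("kup")
  tpl <- fixture_template("kup_template.tsv", ctx)
  run <- function() {
    ctx2 <- fixture_ctx("kup")
    onto <- generate(tpl, ctx2$scripts, ctx2$column_map, ctx2$policy,
                     snapshot = ctx2$snapshot)
    render_manchester(onto)
  }
  expect_identical(run(), run())
})

test_that("generated RDF reparses to the same axiom multiset", {
  ctx <- fixture_ctx("nucleation")
  tpl <- fixture_template("mononucleate_row.tsv", ctx)
  onto <- generate(tpl, ctx$scripts, ctx$column_map, ctx$policy,
                   snapshot = ctx$snapshot)
  for (fmt in c("turtle", "rdfxml")) {
    back <- read_generated_rdf(serialize_rdf(onto, fmt), fmt)
    expect_identical(axiom_signature(back), axiom_signature(onto))
    logical <- ontopop:::logical_axioms(back)
    expect_length(logical, 1L)
    expect_identical(ontopop:::node_kind(logical[[1]]$axiom$object), "op_some")
    # provenance survives the round trip
    expect_identical(logical[[1]]$prov$script, "cell_nucleation.oppl")
  }
  expect_error(serialize_rdf(onto, "n3"), "unknown format")
})

test_that("an axiom-free ontology serializes to a bare header", {
  onto <- structure(list(iri = "http://x/onto", pm = default_prefixes(),
                         axioms = list(), minted = list(), report = NULL),
                    class = "generated_ontology")
  ttl <- serialize_rdf(onto, "turtle")
  back <- read_generated_rdf(ttl, "turtle")
  expect_identical(back$iri, "http://x/onto")
  expect_length(back$axioms, 0L)
})
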