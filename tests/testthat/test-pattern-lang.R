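ex1_text <- function()
  readLines(file.path(fixture_dir(), "cell_anatomy.oppl"), warn = FALSE)
ex2_text <- function()
  readLines(file.path(fixture_dir(), "cell_process.oppl"), warn = FALSE)
ex4_text <- function()
  readLines(file.path(fixture_dir(), "cell_nucleation.oppl"), warn = FALSE)

tref <- function(curie, label = NULL)
  term_ref(pm_expand(default_prefixes(), curie), label = label)

# resolver over the fixture snapshot (bare names like `cell` resolve by label)
fixture_resolver <- function() {
  ctx <- fixture_ctx("kup")
  ontopop:::snapshot_resolver(ctx$snapshot, default_prefixes())
}

test_that("parser recovers the structure of the worked pattern scripts", {
  s4 <- parse_pattern(ex4_text())
  expect_identical(s4$declarations, c("?cell", "?nucleation"))
  expect_length(s4$definitions, 0L)
  expect_length(s4$actions, 1L)
  expect_identical(s4$actions[[1]]$kind, "SubClassOf")

  s1 <- parse_pattern(ex1_text())
  expect_identical(input_variables(s1), c("?cell", "?anatomyPart"))
  expect_identical(names(s1$definitions),
                   c("?partOfRestriction", "?anatomyIntersection"))
  expect_length(s1$actions, 1L)
  expect_identical(s1$actions[[1]]$kind, "EquivalentTo")

  s2 <- parse_pattern(ex2_text())
  expect_identical(input_variables(s2), c("?cell", "?participant"))
  expect_length(
    unique(c(input_variables(s1), input_variables(s2))), 3L)
})

test_that("scripts whose declarations are all defined need no bindings", {
  s <- parse_pattern(
    "?x:CLASS = alpha and beta BEGIN ADD ?x SubClassOf gamma END;")
  expect_length(input_variables(s), 0L)
})

test_that("malformed and unsupported scripts fail with clear errors", {
  expect_error(parse_pattern("BEGIN END;"), "no actions|expected")
  expect_error(parse_pattern("?c:CLASS BEGIN REMOVE ?c SubClassOf x END;"),
               "unsupported OPPL construct 'REMOVE'")
  expect_error(parse_pattern("?c:OBJECTPROPERTY BEGIN ADD ?c SubClassOf x END;"),
               "only CLASS variables")
  expect_error(parse_pattern("?c:CLASS BEGIN ADD ?c SubClassOf ?nope END;"),
               "undeclared variable '\\?nope'")
  err <- tryCatch(parse_pattern("?c:CLASS,\n?d BEGIN END;"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "line 2")
})

test_that("keyword casing is accepted as printed in either variant", {
  a <- parse_pattern("?c:CLASS begin add ?c subclassof x end;")
  b <- parse_pattern("?c:CLASS BEGIN ADD ?c SubClassOf x END;")
  expect_identical(a$actions[[1]]$kind, b$actions[[1]]$kind)
  c1 <- parse_pattern("?c:CLASS BEGIN ADD ?c equivalentTo x END;")
  c2 <- parse_pattern("?c:CLASS BEGIN ADD ?c EquivalentTo x END;")
  expect_identical(c1$actions[[1]]$kind, "EquivalentTo")
  expect_identical(c1$actions[[1]]$kind, c2$actions[[1]]$kind)
})

test_that("pretty-printing round-trips the AST", {
  for (txt in list(ex1_text(), ex2_text(), ex4_text())) {
    s <- parse_pattern(txt, id = "x")
    s2 <- parse_pattern(render_pattern(s), id = "x")
    expect_identical(s2, s)
  }
})

test_that("expansion of the nucleation pattern yields the single restriction axiom", {
  s <- parse_pattern(ex4_text())
  axs <- expand(s, list("?cell" = list(tref("cto:CL_0000113")),
                        "?nucleation" = list(tref("pato:PATO_0001407"))),
                fixture_resolver())
  expect_length(axs, 1L)
  expect_identical(axs[[1]]$kind, "SubClassOf")
  expect_identical(axs[[1]]$subject$curie, "cto:CL_0000113")
  obj <- axs[[1]]$object
  expect_identical(ontopop:::node_kind(obj), "op_some")
  expect_identical(obj$filler$term$curie, "pato:PATO_0001407")
})

test_that("the anatomy pattern builds one unsplit equivalence intersection", {
  s <- parse_pattern(ex1_text())
  axs <- expand(s, list("?cell" = list(tref("kupo:KUPO_0001028")),
                        "?anatomyPart" = list(tref("MA:MA_0002546"))),
                fixture_resolver())
  expect_length(axs, 1L)
  expect_identical(axs[[1]]$kind, "EquivalentTo")
  obj <- axs[[1]]$object
  expect_identical(ontopop:::node_kind(obj), "op_and")
  expect_length(obj$children, 2L)
  expect_identical(obj$children[[1]]$term$curie, "cell:CL_0000000")
  expect_identical(obj$children[[2]]$prop$term$curie, "ro:part_of")
})

test_that("the process pattern splits its subclass intersection per conjunct", {
  s <- parse_pattern(ex2_text())
  gos <- lapply(paste0("gene_ontology:", c("GO_0003093", "GO_0003098",
                                           "GO_0003106")), tref)
  axs <- expand(s, list("?cell" = list(tref("kupo:KUPO_0001028")),
                        "?participant" = gos),
                fixture_resolver())
  expect_length(axs, 4L)
  expect_true(all(vapply(axs, `[[`, "", "kind") == "SubClassOf"))
  rendered <- vapply(axs, function(a)
    ontopop:::manchester_expr(a$object, default_prefixes()), "")
  expect_setequal(rendered, c(
    "cell:CL_0000000",
    "ro:participates_in some gene_ontology:GO_0003093",
    "ro:participates_in some gene_ontology:GO_0003098",
    "ro:participates_in some gene_ontology:GO_0003106"))
})

test_that("macro expansion matches a naive substitution oracle for k <= 5", {
  s <- parse_pattern(ex2_text())
  res <- fixture_resolver()
  pool <- paste0("gene_ontology:", c("GO_0003093", "GO_0003098", "GO_0003106",
                                     "GO_0003014", "GO_0003008"))
  for (k in 0:5) {
    vals <- lapply(pool[seq_len(k)], tref)
    axs <- expand(s, list("?cell" = list(tref("cto:CL_0000653")),
                          "?participant" = vals), res)
    # naive oracle: enumerate the expected superclass strings directly
    expected <- if (k == 0) character(0) else unique(c(
      "cell:CL_0000000",
      vapply(pool[seq_len(k)], function(g)
        paste0("ro:participates_in some ", g), "")))
    got <- vapply(axs, function(a)
      ontopop:::manchester_expr(a$object, default_prefixes()), "")
    expect_setequal(got, expected)
    expect_length(axs, length(expected))
  }
})

test_that("duplicate conjuncts are removed syntactically, preserving first occurrence", {
  s <- parse_pattern(paste(
    "?x:CLASS,",
    "?y:CLASS,",
    "?r:CLASS = alpha and rel_p some ?y,",
    "?i:CLASS = createIntersection(?r.VALUES)",
    "BEGIN ADD ?x SubClassOf ?i END;", sep = "\n"))
  # the same value listed twice feeds the macro: its restriction collapses
  g <- tref("pato:PATO_0001407")
  axs <- expand(s, list("?x" = list(tref("cto:CL_0000113")), "?y" = list(g, g)))
  ks <- vapply(axs, function(a) ontopop:::node_key(a$object), "")
  expect_length(axs, 2L)  # `alpha` plus one deduplicated restriction
  expect_identical(anyDuplicated(ks), 0L)
})

test_that("zero-valued variables suppress axiom emission instead of failing", {
  s <- parse_pattern(ex4_text())
  axs <- expand(s, list("?cell" = list(tref("cto:CL_0000113")),
                        "?nucleation" = list()))
  expect_length(axs, 0L)
  # an unbound (as opposed to empty) input variable is an error
  expect_error(expand(s, list("?cell" = list(tref("cto:CL_0000113")))),
               "no binding")
})

test_that("expansion is deterministic", {
  s <- parse_pattern(ex2_text())
  res <- fixture_resolver()
  b <- list("?cell" = list(tref("kupo:KUPO_0001028")),
            "?participant" = lapply(paste0("gene_ontology:",
                                           c("GO_0003093", "GO_0003098")), tref))
  sig <- function(axs) vapply(axs, function(a)
    paste(a$kind, a$subject$iri, ontopop:::node_key(a$object)), "")
  expect_identical(sig(expand(s, b, res)), sig(expand(s, b, res)))
})
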