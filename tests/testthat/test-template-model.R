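test_that("multi-valued cells split on vertical bars and resolve term by term", {
  ctx <- fixture_ctx("kup")
  go_set <- ctx$validations$D
  cell <- parse_cell(paste0("regulation of glomerular filtration|",
                            "tubuloglomerular feedback|",
                            "regulation of glomerular filtration by angiotensin"),
                     go_set)
  expect_length(cell$tokens, 3L)
  expect_true(all(vapply(cell$tokens, `[[`, "", "status") == "resolved"))
  expect_identical(vapply(cell$tokens, function(t) t$term$curie, ""),
                   paste0("gene_ontology:", c("GO_0003093", "GO_0003098",
                                              "GO_0003106")))

  expect_length(parse_cell("", go_set)$tokens, 0L)
  expect_length(parse_cell(NA_character_, go_set)$tokens, 0L)

  unk <- parse_cell("Proximal tubule epithelial cell",
                    fixture_ctx("nucleation")$validations$A)
  expect_length(unk$tokens, 1L)
  expect_identical(unk$tokens[[1]]$status, "unknown")
})

test_that("cells resolve by CURIE and IRI when the label is not used", {
  ctx <- fixture_ctx("kup")
  cell <- parse_cell("gene_ontology:GO_0003098", ctx$validations$D)
  expect_identical(cell$tokens[[1]]$status, "resolved")
  iri <- pm_expand(default_prefixes(), "gene_ontology:GO_0003098")
  cell2 <- parse_cell(iri, ctx$validations$D)
  expect_identical(cell2$tokens[[1]]$term$iri, iri)
  # without a validation set, resolution needs a snapshot and CURIE/IRI form
  cell3 <- parse_cell("gene_ontology:GO_0003098", snapshot = ctx$snapshot)
  expect_identical(cell3$tokens[[1]]$status, "resolved")
  cell4 <- parse_cell("tubuloglomerular feedback")
  expect_identical(cell4$tokens[[1]]$status, "unknown")
})

test_that("escaped separators stay inside one token", {
  cell <- parse_cell("alpha \\| beta|gamma")
  expect_length(cell$tokens, 2L)
  expect_identical(cell$tokens[[1]]$raw, "alpha | beta")
  expect_identical(cell$tokens[[2]]$raw, "gamma")
})

test_that("token counts and normalization are stable under re-joining", {
  ctx <- fixture_ctx("kup")
  raws <- c("a|b|c", "  x |y ", "single", "p\\|q|r",
            "regulation of glomerular filtration|tubuloglomerular feedback")
  for (raw in raws) {
    cell <- parse_cell(raw, ctx$validations$D)
    n_sep <- lengths(regmatches(raw, gregexpr("(?<!\\\\)\\|", raw, perl = TRUE)))
    expect_length(cell$tokens, 1L + n_sep)
    rejoined <- paste(vapply(cell$tokens, function(t)
      gsub("|", "\\|", t$raw, fixed = TRUE), ""), collapse = "|")
    cell2 <- parse_cell(rejoined, ctx$validations$D)
    expect_identical(vapply(cell2$tokens, `[[`, "", "raw"),
                     vapply(cell$tokens, `[[`, "", "raw"))
  }
})

test_that("autocomplete ranks prefix matches first and refines monotonically", {
  vs <- fixture_ctx("nucleation")$validations$B
  expect_identical(autocomplete("mono", vs)[1], "mononucleate")
  expect_identical(autocomplete("", vs, limit = 3L),
                   utils::head(vapply(vs$members, label_or_fragment, ""), 3L))
  # typing one more character can only filter the previous result list
  all_disp <- vapply(vs$members, label_or_fragment, "")
  for (q in c("n", "nu", "nuc", "m", "mo", "mon")) {
    wider <- autocomplete(q, vs, limit = 100L)
    narrower <- autocomplete(paste0(q, "u"), vs, limit = 100L)
    expect_true(all(narrower %in% wider))
    # brute-force check of membership semantics
    expect_setequal(wider, all_disp[grepl(q, norm_text(all_disp), fixed = TRUE)])
  }
})

test_that("template validation pinpoints invalid tokens by row and column", {
  ctx <- fixture_ctx("nucleation")
  tpl_bad <- fixture_template("nucleation_template.tsv", ctx)
  rep_bad <- validate_template(tpl_bad)
  expect_identical(nrow(rep_bad$unknown), 1L)
  expect_identical(rep_bad$unknown$row, 5L)
  expect_identical(rep_bad$unknown$column, "A")
  expect_identical(rep_bad$unknown$raw, "Proximal tubule epithelial cell")

  tpl_ok <- fixture_template("mononucleate_row.tsv", ctx)
  expect_identical(nrow(validate_template(tpl_ok)$unknown), 0L)
})

test_that("per-column cell counts conserve the row total", {
  ctx <- fixture_ctx("kup")
  tpl <- fixture_template("kup_template.tsv", ctx)
  rep <- validate_template(tpl)
  for (i in seq_len(nrow(rep$counts)))
    expect_identical(rep$counts$resolved[i] + rep$counts$unknown[i] +
                       rep$counts$empty[i],
                     length(tpl$rows))
  # direct tally oracle for one column
  a_cells <- lapply(tpl$rows, `[[`, "A")
  expect_identical(rep$counts$resolved[rep$counts$column == "A"],
                   sum(vapply(a_cells, function(cl)
                     length(cl$tokens) > 0 &&
                       all(vapply(cl$tokens, `[[`, "", "status") == "resolved"),
                     TRUE)))
})

test_that("validation is a pure function of the template", {
  ctx <- fixture_ctx("nucleation")
  tpl <- fixture_template("nucleation_template.tsv", ctx)
  expect_identical(validate_template(tpl), validate_template(tpl))
})

test_that("token-level report serializes to TSV", {
  ctx <- fixture_ctx("nucleation")
  tpl <- fixture_template("nucleation_template.tsv", ctx)
  path <- tempfile(fileext = ".tsv")
  write_report_tsv(validate_template(tpl), tpl, path)
  df <- utils::read.delim(path)
  expect_identical(names(df), c("row", "column", "raw", "status"))
  expect_identical(sum(df$status == "unknown"), 1L)
})
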