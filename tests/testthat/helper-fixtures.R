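# Shared fixture plumbing: the bundle is written once per test session and
# workflow contexts are memoized, so individual tests stay fast.

fixture_dir <- function() {
  d <- file.path(tempdir(), "ontopop-fixtures")
  if (!dir.exists(d)) make_fixtures(d)
  d
}

.ctx_cache <- new.env(parent = emptyenv())

fixture_ctx <- function(which = c("nucleation", "kup")) {
  which <- match.arg(which)
  if (is.null(.ctx_cache[[which]]))
    .ctx_cache[[which]] <- load_workflow_context(
      file.path(fixture_dir(), paste0(which, "_workflow.yaml")))
  ctx <- .ctx_cache[[which]]
  # policies are mutable (mint counters); hand out a fresh one each time
  ctx$policy <- mint_policy(ctx$config$mint$base, ctx$config$mint$prefix_label,
                            width = ctx$config$mint$width,
                            next_index = ctx$config$mint$next_index,
                            reserved = names(ctx$snapshot$terms))
  ctx
}

fixture_template <- function(name, ctx) {
  read_template_tsv(file.path(fixture_dir(), name),
                    validations = ctx$validations, snapshot = ctx$snapshot)
}

# whitespace-collapsed, case-folded text for Manchester frame comparisons
norm_text <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

# independent reachability oracle over a snapshot's edge tables (igraph
# breadth-first search; the implementation under test uses its own
# visited-set traversal)
oracle_descendants <- function(snapshot, root_iri, relations) {
  edges <- character(0)
  if ("subclass" %in% relations) {
    sub <- snapshot$subclass
    edges <- c(edges, rbind(sub$parent, sub$child))
  }
  if ("part-of" %in% relations) {
    po <- partof_edges(snapshot)
    edges <- c(edges, rbind(po$whole, po$part))
  }
  nodes <- unique(c(names(snapshot$terms), edges))
  g <- igraph::make_graph(edges = match(edges, nodes), n = length(nodes),
                          directed = TRUE)
  reach <- igraph::subcomponent(g, match(root_iri, nodes), mode = "out")
  setdiff(nodes[as.integer(reach)], root_iri)
}

member_iris <- function(vset) vapply(vset$members, `[[`, "", "iri")

expected_frame_lines <- function(text, lines) {
  hay <- norm_text(text)
  all(vapply(lines, function(l) grepl(norm_text(l), hay, fixed = TRUE), TRUE))
}
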