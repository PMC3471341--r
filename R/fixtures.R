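# Fixture bundle: miniature vocabularies and templates that make every
# worked example runnable offline, written deterministically in both OBO
# and Turtle so both loaders are exercised. Only a handful of terms are
# fixed by the worked examples (the CTO root "cell", "mononuclear
# phagocyte", "mononucleate", MA_0002546 and the three glomerular-filtration
# GO terms); the surrounding terms are synthetic filler chosen to look like
# their source vocabularies.

fixture_tables <- function() {
  list(
    cto = list(
      ontology = "cto",
      terms = data.frame(
        id = c("cell:CL_0000000", "cto:CL_0000066", "cto:CL_0000113",
               "cto:CL_0000182", "cto:CL_0000232", "cto:CL_0000235",
               "cto:CL_0000540", "cto:CL_0000542", "cto:CL_0000576",
               "cto:CL_0000650", "cto:CL_0000653"),
        name = c("cell", "epithelial cell", "mononuclear phagocyte",
                 "hepatocyte", "erythrocyte", "macrophage", "neuron",
                 "lymphocyte", "monocyte", "mesangial cell", "podocyte"),
        is_a = c("", rep("cell:CL_0000000", 10)),
        partof = "",
        stringsAsFactors = FALSE)),
    pato = list(
      ontology = "pato",
      terms = data.frame(
        id = c("pato:PATO_0001404", "pato:PATO_0001405", "pato:PATO_0001406",
               "pato:PATO_0001407", "pato:PATO_0001908"),
        name = c("nucleation", "anucleate", "binucleate", "mononucleate",
                 "multinucleate"),
        is_a = c("", rep("pato:PATO_0001404", 4)),
        partof = "",
        stringsAsFactors = FALSE)),
    ma = list(
      ontology = "ma",
      terms = data.frame(
        id = c("MA:MA_0000325", "MA:MA_0000368", "MA:MA_0000378",
               "MA:MA_0000380", "MA:MA_0001652", "MA:MA_0001653",
               "MA:MA_0001656", "MA:MA_0001657", "MA:MA_0001660",
               "MA:MA_0002546"),
        name = c("urinary system", "kidney", "ureter", "urinary bladder",
                 "renal cortex", "renal medulla", "nephron",
                 "renal glomerulus", "afferent arteriole",
                 "part of afferent arteriole forming juxtaglomerular complex"),
        is_a = "",
        partof = c("", "MA:MA_0000325", "MA:MA_0000325", "MA:MA_0000325",
                   "MA:MA_0000368", "MA:MA_0000368", "MA:MA_0001652",
                   "MA:MA_0001656", "MA:MA_0001652", "MA:MA_0001660"),
        stringsAsFactors = FALSE)),
    go = list(
      ontology = "go",
      terms = data.frame(
        id = c("gene_ontology:GO_0008150", "gene_ontology:GO_0003008",
               "gene_ontology:GO_0003014", "gene_ontology:GO_0003093",
               "gene_ontology:GO_0003098", "gene_ontology:GO_0003106"),
        name = c("biological_process", "system process",
                 "renal system process", "regulation of glomerular filtration",
                 "tubuloglomerular feedback",
                 "regulation of glomerular filtration by angiotensin"),
        is_a = c("", "gene_ontology:GO_0008150", "gene_ontology:GO_0003008",
                 "gene_ontology:GO_0003014", "gene_ontology:GO_0003093",
                 "gene_ontology:GO_0003093"),
        partof = "",
        stringsAsFactors = FALSE))
  )
}

fixture_relations <- function() {
  data.frame(
    id = c("ro:part_of", "ro:participates_in", "hasNucleation"),
    name = c("part of", "participates in", "has nucleation"),
    stringsAsFactors = FALSE)
}

table_to_obo <- function(tab, relations = NULL) {
  out <- c("format-version: 1.2", paste0("ontology: ", tab$ontology), "")
  for (i in seq_len(nrow(tab$terms))) {
    t <- tab$terms[i, ]
    out <- c(out, "[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (nzchar(t$is_a)) out <- c(out, paste0("is_a: ", t$is_a))
    if (nzchar(t$partof)) out <- c(out, paste0("relationship: ro:part_of ", t$partof))
    out <- c(out, "")
  }
  if (!is.null(relations)) {
    for (i in seq_len(nrow(relations))) {
      out <- c(out, "[Typedef]", paste0("id: ", relations$id[i]),
               paste0("name: ", relations$name[i]), "")
    }
  }
  paste(out, collapse = "\n")
}

table_to_turtle <- function(tab, pm = default_prefixes()) {
  used <- unique(c(sub(":.*", "", grep(":", c(tab$terms$id, tab$terms$is_a,
                                              tab$terms$partof), value = TRUE)),
                   if (any(nzchar(tab$terms$partof))) "ro"))
  out <- c(paste0("@prefix owl: <", OWL, "> ."),
           paste0("@prefix rdfs: <", RDFS, "> ."),
           vapply(used, function(p) paste0("@prefix ", p, ": <",
                                           pm[[which(names(pm) == p)]], "> ."), ""),
           "",
           paste0("<http://purl.org/obo/owl/", tab$ontology, "> a owl:Ontology ."),
           "")
  for (i in seq_len(nrow(tab$terms))) {
    t <- tab$terms[i, ]
    entries <- c("a owl:Class",
                 paste0("rdfs:label \"", turtle_escape(t$name), "\""))
    if (nzchar(t$is_a))
      entries <- c(entries, paste0("rdfs:subClassOf ", t$is_a))
    if (nzchar(t$partof))
      entries <- c(entries, paste0("rdfs:subClassOf [ a owl:Restriction ; ",
                                   "owl:onProperty ro:part_of ; ",
                                   "owl:someValuesFrom ", t$partof, " ]"))
    out <- c(out, paste0(t$id, "\n",
                         paste0("    ", entries, collapse = " ;\n"), " ."), "")
  }
  paste(out, collapse = "\n")
}

relations_to_turtle <- function(rel, pm = default_prefixes()) {
  out <- c(paste0("@prefix owl: <", OWL, "> ."),
           paste0("@prefix rdfs: <", RDFS, "> ."),
           paste0("@prefix ro: <", pm[[which(names(pm) == "ro")]], "> ."),
           paste0("@prefix rel: <", pm[[which(names(pm) == "")]], "> ."),
           "",
           "<http://purl.org/obo/owl/relations> a owl:Ontology .",
           "")
  for (i in seq_len(nrow(rel))) {
    curie <- if (grepl(":", rel$id[i])) rel$id[i] else paste0("rel:", rel$id[i])
    out <- c(out, paste0(curie, " a owl:ObjectProperty ;\n    rdfs:label \"",
                         rel$name[i], "\" ."), "")
  }
  paste(out, collapse = "\n")
}

fixture_scripts <- function() {
  list(
    cell_anatomy.oppl = paste(
      "?cell:CLASS,",
      "?anatomyPart:CLASS,",
      "?partOfRestriction:CLASS = cell and ro:part_of some ?anatomyPart,",
      "?anatomyIntersection:CLASS = createIntersection(?partOfRestriction.VALUES)",
      "BEGIN",
      "ADD ?cell equivalentTo ?anatomyIntersection",
      "END;", sep = "\n"),
    cell_process.oppl = paste(
      "?cell:CLASS,",
      "?participant:CLASS,",
      "?participatesRestriction:CLASS = cell and ro:participates_in some ?participant,",
      "?participatesIntersection:CLASS = createIntersection(?participatesRestriction.VALUES)",
      "BEGIN",
      "ADD ?cell SubClassOf ?participatesIntersection",
      "END;", sep = "\n"),
    cell_nucleation.oppl = paste(
      "?cell:CLASS,",
      "?nucleation:CLASS",
      "BEGIN",
      "ADD ?cell SubClassOf hasNucleation some ?nucleation",
      "END;", sep = "\n"))
}

fixture_templates <- function() {
  kup_filler <- c(
    "podocyte\trenal glomerulus\tregulation of glomerular filtration",
    "mesangial cell\trenal glomerulus\tregulation of glomerular filtration",
    "epithelial cell\tnephron\trenal system process",
    "macrophage\trenal cortex\tsystem process",
    "monocyte\trenal medulla\tsystem process",
    "lymphocyte\tkidney\tsystem process",
    "erythrocyte\tafferent arteriole\tsystem process",
    "neuron\tkidney\tsystem process",
    "hepatocyte\tkidney\tsystem process",
    "epithelial cell\tureter\trenal system process",
    "epithelial cell\turinary bladder\trenal system process",
    "podocyte\tnephron\ttubuloglomerular feedback")
  list(
    nucleation_template.tsv = paste(c(
      "A\tB",
      "hepatocyte\tmononucleate",
      "erythrocyte\tanucleate",
      "macrophage\tmononucleate",
      "monocyte\tmononucleate",
      "Proximal tubule epithelial cell\tmononucleate",
      "Mononuclear phagocyte\tmononucleate"), collapse = "\n"),
    mononucleate_row.tsv = "A\tB\nMononuclear phagocyte\tmononucleate",
    kup_template.tsv = paste(c(
      "A\tC\tD",
      kup_filler,
      paste0("Juxtaglomerular complex cell\t",
             "part of afferent arteriole forming juxtaglomerular complex\t",
             "regulation of glomerular filtration|tubuloglomerular feedback|",
             "regulation of glomerular filtration by angiotensin")),
      collapse = "\n"))
}

fixture_workflows <- function() {
  list(
    nucleation_workflow.yaml = workflow_config(
      ontologies = list(list(path = "mini-cto.obo", dialect = "obo"),
                        list(path = "mini-pato.obo", dialect = "obo"),
                        list(path = "relations.ttl", dialect = "turtle")),
      ranges = list(
        A = list(root = "cell:CL_0000000", selector = "all-subclasses",
                 traversal_relations = list("subclass")),
        B = list(root = "pato:PATO_0001404", selector = "all-subclasses",
                 traversal_relations = list("subclass"))),
      scripts = "cell_nucleation.oppl",
      variable_map = c("?cell" = "A", "?nucleation" = "B"),
      mint = list(base = "http://purl.org/obo/owl/kupo#", prefix_label = "kupo",
                  width = 7L, next_index = 1L),
      identifier = "nucleation"),
    kup_workflow.yaml = workflow_config(
      ontologies = list(list(path = "mini-cto.ttl", dialect = "turtle"),
                        list(path = "mini-ma.ttl", dialect = "turtle"),
                        list(path = "mini-go.ttl", dialect = "turtle"),
                        list(path = "relations.ttl", dialect = "turtle")),
      ranges = list(
        A = list(root = "cell:CL_0000000", selector = "all-subclasses",
                 traversal_relations = list("subclass")),
        C = list(root = "MA:MA_0000325", selector = "all-subclasses",
                 traversal_relations = list("subclass", "part-of")),
        D = list(root = "gene_ontology:GO_0008150", selector = "all-subclasses",
                 traversal_relations = list("subclass"))),
      scripts = c("cell_anatomy.oppl", "cell_process.oppl"),
      variable_map = c("?cell" = "A", "?anatomyPart" = "C", "?participant" = "D"),
      mint = list(base = "http://purl.org/obo/owl/kupo#", prefix_label = "kupo",
                  width = 7L, next_index = 1028L),
      identifier = "kup"))
}

#' Write the fixture bundle
#'
#' Emits the miniature vocabularies (each in OBO and Turtle), the relation
#' file, the example templates, the three pattern scripts and two workflow
#' configurations, plus a `manifest.tsv` listing every file with its MD5
#' digest. Generation is deterministic.
#'
#' @param dir output directory (created if missing).
#' @param force overwrite a non-empty directory.
#' @param seed accepted for interface uniformity; the bundle is fully
#'   deterministic.
#' @return invisibly, a character vector of the written paths.
#' @export
make_fixtures <- function(dir, force = FALSE, seed = 1L) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force)
    stop("make_fixtures: directory '", dir, "' is not empty (use force = TRUE)",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(name, text) {
    p <- file.path(dir, name)
    writeLines(text, p)
    files <<- c(files, p)
  }
  tabs <- fixture_tables()
  rel <- fixture_relations()
  put("mini-cto.obo", table_to_obo(tabs$cto))
  put("mini-pato.obo", table_to_obo(tabs$pato))
  put("mini-ma.obo", table_to_obo(tabs$ma))
  put("mini-go.obo", table_to_obo(tabs$go))
  put("relations.obo", table_to_obo(list(ontology = "relations",
                                         terms = data.frame(id = character(),
                                                            name = character(),
                                                            is_a = character(),
                                                            partof = character())),
                                    relations = rel))
  put("mini-cto.ttl", table_to_turtle(tabs$cto))
  put("mini-pato.ttl", table_to_turtle(tabs$pato))
  put("mini-ma.ttl", table_to_turtle(tabs$ma))
  put("mini-go.ttl", table_to_turtle(tabs$go))
  put("relations.ttl", relations_to_turtle(rel))
  for (nm in names(fixture_scripts())) put(nm, fixture_scripts()[[nm]])
  for (nm in names(fixture_templates())) put(nm, fixture_templates()[[nm]])
  wf <- fixture_workflows()
  for (nm in names(wf)) save_workflow(wf[[nm]], file.path(dir, nm))
  files <- c(files, file.path(dir, names(wf)))

  digests <- tools::md5sum(sort(files))
  manifest <- data.frame(file = basename(names(digests)), md5 = unname(digests),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(sort(files), file.path(dir, "manifest.tsv")))
}

# ---- synthetic inputs for property checks ---------------------------------

#' Random DAG snapshot
#'
#' Generates an acyclic term hierarchy: `n` classes, each non-root term
#' drawing subclass parents (and optionally part-of wholes) uniformly from
#' earlier terms. Used to compare range resolution against independent
#' reachability computations.
#'
#' @param n number of terms.
#' @param seed RNG seed.
#' @param p_edge probability of each candidate extra edge beyond the first.
#' @param partof also generate a part-of edge layer.
#' @return an `ontology_snapshot`.
#' @export
random_dag_snapshot <- function(n = 50L, seed = 1L, p_edge = 0.05,
                                partof = TRUE) {
  set.seed(seed)
  pm <- default_prefixes()
  base <- "http://purl.org/ontopop/synthetic#"
  iris <- sprintf("%sT%04d", base, seq_len(n))
  terms <- stats::setNames(lapply(seq_len(n), function(i)
    term_ref(iris[i], label = sprintf("synthetic term %04d", i),
             source_ontology = paste0(base, "ontology"), pm = pm)), iris)
  sub_c <- character(); sub_p <- character()
  po_s <- character(); po_o <- character()
  for (i in 2:n) {
    # at least one subclass parent keeps the graph connected
    parents <- unique(c(sample.int(i - 1L, 1L),
                        which(stats::runif(i - 1L) < p_edge)))
    for (p in parents) { sub_c <- c(sub_c, iris[i]); sub_p <- c(sub_p, iris[p]) }
    if (partof && stats::runif(1) < 0.3) {
      w <- sample.int(i - 1L, 1L)
      po_s <- c(po_s, iris[i]); po_o <- c(po_o, iris[w])
    }
  }
  new_snapshot(terms, iris, character(), character(),
               data.frame(child = sub_c, parent = sub_p, stringsAsFactors = FALSE),
               data.frame(individual = character(), class = character(),
                          stringsAsFactors = FALSE),
               data.frame(subject = po_s,
                          property = rep(paste0(pm[[which(names(pm) == "ro")]],
                                                "part_of"), length(po_s)),
                          object = po_o, stringsAsFactors = FALSE),
               paste0(base, "ontology"), pm)
}

#' Random generated ontology
#'
#' Draws a small random axiom list (named superclasses, existential
#' restrictions, intersections; SubClassOf and EquivalentTo) with
#' provenance tags. Used to check that RDF serialization followed by
#' parsing is a fixpoint at the axiom level.
#'
#' @param seed RNG seed.
#' @param n_axioms number of logical axioms.
#' @return a `generated_ontology`.
#' @export
random_generated_ontology <- function(seed = 1L, n_axioms = 8L) {
  set.seed(seed)
  pm <- default_prefixes()
  base <- "http://purl.org/ontopop/synthetic#"
  cls <- sprintf("%sC%02d", base, 1:12)
  props <- sprintf("%sp%d", base, 1:3)
  rnd_named <- function() op_term(term_ref(sample(cls, 1L), pm = pm))
  rnd_some <- function() op_some(op_term(term_ref(sample(props, 1L), pm = pm)),
                                 rnd_named())
  rnd_expr <- function() {
    k <- sample.int(3L, 1L)
    if (k == 1L) rnd_named()
    else if (k == 2L) rnd_some()
    else {
      parts <- lapply(seq_len(sample(2:3, 1L)), function(i)
        if (stats::runif(1) < 0.5) rnd_named() else rnd_some())
      make_intersection(parts)
    }
  }
  axioms <- lapply(seq_len(n_axioms), function(i) {
    kind <- if (stats::runif(1) < 0.7) "SubClassOf" else "EquivalentTo"
    list(axiom = new_axiom(kind, term_ref(sample(cls, 1L), pm = pm), rnd_expr()),
         prov = provenance_tag("synthetic", i, "random",
                               "1970-01-01T00:00:00Z"))
  })
  structure(list(iri = paste0(base, "random-ontology"), pm = pm,
                 axioms = axioms, minted = list(), report = NULL),
            class = "generated_ontology")
}
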