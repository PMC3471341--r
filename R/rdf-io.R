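# Serialization of generated ontologies to Turtle / RDF/XML and the
# corresponding axiom-level reader. Both writers go through one triple
# table (standard OWL-in-RDF mapping: restrictions as blank Restriction
# nodes, intersections as owl:intersectionOf collections written out as
# rdf:first/rdf:rest chains, provenance as owl:Axiom annotations), so the
# reader's triple walk is dialect-independent.

ONTOPOP_PROV <- "http://purl.org/ontopop/provenance#"

node_iri <- function(node, pm) {
  if (node_kind(node) == "op_term") return(node$term$iri)
  if (node_kind(node) == "op_named") {
    iri <- pm_expand(pm, node$name)
    if (is.na(iri)) stop("serialize: cannot resolve name '", node$name, "'",
                         call. = FALSE)
    return(iri)
  }
  stop("node_iri: not a named node", call. = FALSE)
}

onto_triples <- function(onto) {
  pm <- onto$pm
  rows <- list()
  bn <- 0L
  emit <- function(s, p, o, lit = FALSE)
    rows[[length(rows) + 1L]] <<- list(s = s, p = p, o = o, lit = lit)
  blank <- function() { bn <<- bn + 1L; paste0("_:b", bn) }

  # returns the node's id (IRI or blank), emitting structure triples
  write_node <- function(node) {
    k <- node_kind(node)
    if (k %in% c("op_term", "op_named")) return(node_iri(node, pm))
    if (k == "op_some") {
      b <- blank()
      emit(b, paste0(RDF, "type"), paste0(OWL, "Restriction"))
      emit(b, paste0(OWL, "onProperty"), node_iri(node$prop, pm))
      emit(b, paste0(OWL, "someValuesFrom"), write_node(node$filler))
      return(b)
    }
    if (k == "op_and") {
      b <- blank()
      emit(b, paste0(RDF, "type"), paste0(OWL, "Class"))
      ids <- vapply(node$children, write_node, "")
      cells <- vapply(seq_along(ids), function(i) blank(), "")
      emit(b, paste0(OWL, "intersectionOf"), cells[1])
      for (i in seq_along(ids)) {
        emit(cells[i], paste0(RDF, "first"), ids[i])
        emit(cells[i], paste0(RDF, "rest"),
             if (i < length(ids)) cells[i + 1L] else paste0(RDF, "nil"))
      }
      return(b)
    }
    stop("serialize: unexpected node kind ", k, call. = FALSE)
  }

  emit(onto$iri, paste0(RDF, "type"), paste0(OWL, "Ontology"))
  for (entry in onto$axioms) {
    ax <- entry$axiom
    s <- ax$subject$iri
    prop <- switch(ax$kind,
                   SubClassOf = paste0(RDFS, "subClassOf"),
                   EquivalentTo = paste0(OWL, "equivalentClass"),
                   Declaration = paste0(RDF, "type"),
                   AnnotationAssertion = ax$annotation$property)
    if (ax$kind == "Declaration") {
      emit(s, prop, paste0(OWL, "Class"))
      target <- paste0(OWL, "Class"); target_lit <- FALSE
    } else if (ax$kind == "AnnotationAssertion") {
      emit(s, prop, ax$annotation$value, lit = TRUE)
      target <- ax$annotation$value; target_lit <- TRUE
    } else {
      target <- write_node(ax$object); target_lit <- FALSE
      emit(s, prop, target)
    }
    if (!is.null(entry$prov) && ax$kind %in% c("SubClassOf", "EquivalentTo")) {
      a <- blank()
      emit(a, paste0(RDF, "type"), paste0(OWL, "Axiom"))
      emit(a, paste0(OWL, "annotatedSource"), s)
      emit(a, paste0(OWL, "annotatedProperty"), prop)
      emit(a, paste0(OWL, "annotatedTarget"), target, lit = target_lit)
      emit(a, paste0(ONTOPOP_PROV, "template"), entry$prov$template, lit = TRUE)
      emit(a, paste0(ONTOPOP_PROV, "row"), as.character(entry$prov$row), lit = TRUE)
      emit(a, paste0(ONTOPOP_PROV, "script"), entry$prov$script, lit = TRUE)
      emit(a, paste0(ONTOPOP_PROV, "timestamp"), entry$prov$timestamp, lit = TRUE)
    }
  }
  triple_df(vapply(rows, `[[`, "", "s"), vapply(rows, `[[`, "", "p"),
            vapply(rows, `[[`, "", "o"), vapply(rows, function(r) r$lit, TRUE))
}

serialize_pm <- function(pm) {
  c(unclass(pm)[nzchar(names(pm))],
    stats::setNames(ONTOPOP_PROV, "oppv"))
}

ttl_ref <- function(x, ns) {
  if (startsWith(x, "_:")) return(x)
  hit <- startsWith(x, ns)
  if (any(hit)) {
    lens <- ifelse(hit, nchar(ns), -1L)
    best <- which.max(lens)
    local <- substr(x, nchar(ns[best]) + 1L, nchar(x))
    if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local))
      return(paste0(names(ns)[best], ":", local))
  }
  paste0("<", x, ">")
}

write_turtle_triples <- function(tri, pm) {
  ns <- serialize_pm(pm)
  out <- vapply(seq_along(ns), function(i)
    paste0("@prefix ", names(ns)[i], ": <", ns[[i]], "> ."), "")
  out <- c(out, "")
  # group consecutive triples by subject for readability
  i <- 1L
  while (i <= nrow(tri)) {
    s <- tri$s[i]
    j <- i
    while (j < nrow(tri) && tri$s[j + 1L] == s) j <- j + 1L
    lines <- vapply(i:j, function(k) {
      o <- if (tri$o_literal[k]) paste0("\"", turtle_escape(tri$o[k]), "\"")
           else ttl_ref(tri$o[k], ns)
      paste0("    ", ttl_ref(tri$p[k], ns), " ", o)
    }, "")
    out <- c(out, paste0(ttl_ref(s, ns), "\n",
                         paste(lines, collapse = " ;\n"), " ."))
    i <- j + 1L
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

rdfxml_qname <- function(iri) {
  vocab <- c(rdf = RDF, rdfs = RDFS, owl = OWL, oppv = ONTOPOP_PROV)
  for (p in names(vocab))
    if (startsWith(iri, vocab[[p]]))
      return(paste0(p, ":", substr(iri, nchar(vocab[[p]]) + 1L, nchar(iri))))
  stop("rdfxml: predicate outside known vocabularies: ", iri, call. = FALSE)
}

write_rdfxml_triples <- function(tri) {
  head <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<rdf:RDF xmlns:rdf=\"", RDF, "\"\n",
    "         xmlns:rdfs=\"", RDFS, "\"\n",
    "         xmlns:owl=\"", OWL, "\"\n",
    "         xmlns:oppv=\"", ONTOPOP_PROV, "\">")
  body <- character()
  i <- 1L
  while (i <= nrow(tri)) {
    s <- tri$s[i]
    j <- i
    while (j < nrow(tri) && tri$s[j + 1L] == s) j <- j + 1L
    about <- if (startsWith(s, "_:"))
      paste0("rdf:nodeID=\"", substr(s, 3L, nchar(s)), "\"")
    else paste0("rdf:about=\"", xml_escape(s), "\"")
    props <- vapply(i:j, function(k) {
      qn <- rdfxml_qname(tri$p[k])
      if (tri$o_literal[k])
        paste0("    <", qn, ">", xml_escape(tri$o[k]), "</", qn, ">")
      else if (startsWith(tri$o[k], "_:"))
        paste0("    <", qn, " rdf:nodeID=\"", substr(tri$o[k], 3L, nchar(tri$o[k])),
               "\"/>")
      else
        paste0("    <", qn, " rdf:resource=\"", xml_escape(tri$o[k]), "\"/>")
    }, "")
    body <- c(body, paste0("  <rdf:Description ", about, ">"),
              paste0("  ", props), "  </rdf:Description>")
    i <- j + 1L
  }
  paste0(head, "\n", paste(body, collapse = "\n"), "\n</rdf:RDF>\n")
}

#' Serialize a generated ontology to RDF
#'
#' Standard OWL mapping: `SubClassOf` becomes `rdfs:subClassOf` (existential
#' restrictions as blank `owl:Restriction` nodes with
#' `owl:onProperty`/`owl:someValuesFrom`), `EquivalentTo` becomes
#' `owl:equivalentClass` with an `owl:intersectionOf` list for
#' intersections. Provenance tags are written as `owl:Axiom` annotations.
#' Re-parsing the document with [read_generated_rdf] yields the same axiom
#' multiset.
#'
#' @param onto a `generated_ontology`.
#' @param format `"turtle"` or `"rdfxml"`.
#' @param path optional output file; when `NULL` the document text is
#'   returned.
#' @return document text (invisibly when `path` is given).
#' @export
serialize_rdf <- function(onto, format = c("turtle", "rdfxml"), path = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("serialize_rdf: unknown format '",
                                              format[1], "'", call. = FALSE))
  tri <- onto_triples(onto)
  text <- if (format == "turtle") write_turtle_triples(tri, onto$pm)
          else write_rdfxml_triples(tri)
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

#' Read a generated-ontology RDF document back into axioms
#'
#' Reconstructs the `generated_ontology` axiom list (SubClassOf,
#' EquivalentTo, Declaration, label AnnotationAssertion) from a document
#' written by [serialize_rdf], including provenance annotations when
#' present.
#'
#' @param source path or document text.
#' @param format `"turtle"` or `"rdfxml"`.
#' @param pm `prefix_map` for the reconstructed ontology.
#' @return a `generated_ontology`.
#' @export
read_generated_rdf <- function(source, format = c("turtle", "rdfxml"),
                               pm = default_prefixes()) {
  format <- match.arg(format)
  is_path <- length(source) == 1L && !grepl("\n", source) && file.exists(source)
  text <- if (is_path) paste(readLines(source, warn = FALSE), collapse = "\n") else
    paste(source, collapse = "\n")
  tri <- if (format == "turtle") parse_turtle(text) else parse_rdfxml(text)

  is_blank <- function(x) startsWith(x, "_:")
  p_of <- function(s, p) tri$o[tri$s == s & tri$p == p]
  typ <- tri[tri$p == paste0(RDF, "type"), ]

  onto_sub <- typ$s[typ$o == paste0(OWL, "Ontology")]
  onto_iri <- if (length(onto_sub)) onto_sub[1] else "urn:ontopop:parsed"
  axiom_nodes <- typ$s[typ$o == paste0(OWL, "Axiom")]

  read_node <- function(id) {
    if (!is_blank(id))
      return(op_term(term_ref(id, source_ontology = onto_iri, pm = pm)))
    types <- p_of(id, paste0(RDF, "type"))
    if (paste0(OWL, "Restriction") %in% types) {
      prop <- p_of(id, paste0(OWL, "onProperty"))[1]
      filler <- p_of(id, paste0(OWL, "someValuesFrom"))[1]
      return(op_some(op_term(term_ref(prop, pm = pm)), read_node(filler)))
    }
    lst <- p_of(id, paste0(OWL, "intersectionOf"))
    if (length(lst)) {
      items <- list()
      cur <- lst[1]
      while (cur != paste0(RDF, "nil")) {
        items[[length(items) + 1L]] <- read_node(p_of(cur, paste0(RDF, "first"))[1])
        cur <- p_of(cur, paste0(RDF, "rest"))[1]
      }
      return(op_and(items))
    }
    stop("read_generated_rdf: uninterpretable blank node ", id, call. = FALSE)
  }

  # provenance lookup keyed by source/property (target shapes are blank-node
  # ids, which do not survive the round trip; source+property identifies the
  # axiom well enough to re-attach tags, duplicates resolved in order)
  prov_entries <- lapply(axiom_nodes, function(a) {
    g <- function(p) { v <- p_of(a, paste0(ONTOPOP_PROV, p)); if (length(v)) v[1] else NA_character_ }
    list(src = p_of(a, paste0(OWL, "annotatedSource"))[1],
         prop = p_of(a, paste0(OWL, "annotatedProperty"))[1],
         tag = provenance_tag(g("template"), as.integer(g("row")), g("script"),
                              g("timestamp")))
  })
  take_prov <- function(src, prop) {
    for (i in seq_along(prov_entries)) {
      e <- prov_entries[[i]]
      if (!is.null(e) && e$src == src && e$prop == prop) {
        prov_entries[[i]] <<- NULL
        return(e$tag)
      }
    }
    NULL
  }

  axioms <- list()
  add <- function(ax, prov) axioms[[length(axioms) + 1L]] <<- list(axiom = ax, prov = prov)
  skip <- c(axiom_nodes)
  for (k in seq_len(nrow(tri))) {
    s <- tri$s[k]; p <- tri$p[k]; o <- tri$o[k]
    if (s %in% skip || is_blank(s)) next
    if (p == paste0(RDF, "type") && o == paste0(OWL, "Class") && !tri$o_literal[k]) {
      add(new_axiom("Declaration", term_ref(s, source_ontology = onto_iri, pm = pm)), NULL)
    } else if (p == paste0(RDFS, "label") && tri$o_literal[k]) {
      add(new_axiom("AnnotationAssertion", term_ref(s, pm = pm),
                    annotation = list(property = paste0(RDFS, "label"), value = o)),
          NULL)
    } else if (p == paste0(RDFS, "subClassOf")) {
      add(new_axiom("SubClassOf", term_ref(s, pm = pm), read_node(o)),
          take_prov(s, p))
    } else if (p == paste0(OWL, "equivalentClass")) {
      add(new_axiom("EquivalentTo", term_ref(s, pm = pm), read_node(o)),
          take_prov(s, p))
    }
  }
  structure(list(iri = onto_iri, pm = pm, axioms = axioms, minted = list(),
                 report = NULL),
            class = "generated_ontology")
}

#' Axiom multiset signature of a generated ontology
#'
#' Sorted vector of `kind|subject|object-key` strings; two ontologies with
#' equal signatures carry the same logical content.
#'
#' @param onto a `generated_ontology`.
#' @param logical_only drop Declaration/AnnotationAssertion entries.
#' @return sorted character vector.
#' @export
axiom_signature <- function(onto, logical_only = FALSE) {
  axs <- if (logical_only) logical_axioms(onto) else onto$axioms
  sort(vapply(axs, function(a) {
    obj <- if (!is.null(a$axiom$object)) node_key(a$axiom$object)
           else if (!is.null(a$axiom$annotation)) a$axiom$annotation$value
           else ""
    paste(a$axiom$kind, a$axiom$subject$iri, obj, sep = "|")
  }, ""))
}
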