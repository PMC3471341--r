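#' Load a vocabulary into an ontology snapshot
#'
#' Parses an OBO flat file, a Turtle document or an RDF/XML document into an
#' indexed snapshot of its asserted content: one [term_ref] per declared
#' class, individual and object property, plus subclass, instance-of and
#' relationship (notably part-of) edge tables. No reasoning is performed;
#' all downstream range resolution works over these told edges.
#'
#' @param source path to the document, or a character scalar holding its text
#'   (anything containing a newline is treated as text).
#' @param dialect one of `"obo"`, `"turtle"`, `"rdfxml"`.
#' @param pm `prefix_map` used to contract IRIs and expand OBO ids.
#' @return an object of class `ontology_snapshot` with fields `terms`
#'   (named list of [term_ref] keyed by IRI), `classes`, `individuals`,
#'   `properties` (IRI vectors), `subclass` (`child`,`parent`), `instance`
#'   (`individual`,`class`), `relationship` (`subject`,`property`,`object`)
#'   and `ontology_iri`.
#' @examples
#' obo <- "format-version: 1.2\n\n[Term]\nid: pato:PATO_0001407\nname: mononucleate\n"
#' snap <- load_ontology(obo, "obo")
#' snap$terms[[1]]$label
#' @export
load_ontology <- function(source, dialect = c("obo", "turtle", "rdfxml"),
                          pm = default_prefixes()) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("load_ontology: unknown dialect '",
                                               dialect[1], "'", call. = FALSE))
  is_path <- length(source) == 1L && !grepl("\n", source) && file.exists(source)
  text <- if (is_path) paste(readLines(source, warn = FALSE), collapse = "\n") else
    paste(source, collapse = "\n")
  doc_iri <- if (is_path) paste0("file://", normalizePath(source)) else "urn:ontopop:inline"

  if (dialect == "obo") return(snapshot_from_obo(text, pm, doc_iri))
  tri <- if (dialect == "turtle") parse_turtle(text) else parse_rdfxml(text)
  snapshot_from_triples(tri, pm, doc_iri)
}

new_snapshot <- function(terms, classes, individuals, properties,
                         subclass, instance, relationship, ontology_iri, pm) {
  structure(
    list(terms = terms, classes = classes, individuals = individuals,
         properties = properties, subclass = subclass, instance = instance,
         relationship = relationship, ontology_iri = ontology_iri, pm = pm),
    class = "ontology_snapshot"
  )
}

#' @export
print.ontology_snapshot <- function(x, ...) {
  cat("<ontology_snapshot> ", x$ontology_iri, "\n",
      "  terms: ", length(x$terms),
      " (", length(x$classes), " classes, ", length(x$individuals),
      " individuals, ", length(x$properties), " properties)\n",
      "  edges: ", nrow(x$subclass), " subclass, ",
      nrow(partof_edges(x)), " part-of, ", nrow(x$instance), " instance-of\n",
      sep = "")
  invisible(x)
}

#' Part-of edge table of a snapshot
#'
#' @param snapshot an `ontology_snapshot`.
#' @return data frame with columns `part`, `whole`.
#' @export
partof_edges <- function(snapshot) {
  rel <- snapshot$relationship
  keep <- iri_fragment(rel$property) == "part_of"
  data.frame(part = rel$subject[keep], whole = rel$object[keep],
             stringsAsFactors = FALSE)
}

# ---- OBO flat file --------------------------------------------------------

snapshot_from_obo <- function(text, pm, doc_iri) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("\\s*!.*$", "", lines)          # trailing comments
  stanza <- NA_character_
  cur <- NULL
  terms <- list(); classes <- character(); properties <- character()
  sub_c <- character(); sub_p <- character()
  rel_s <- character(); rel_p <- character(); rel_o <- character()
  onto_iri <- doc_iri

  expand_id <- function(id) {
    iri <- pm_expand(pm, id)
    if (is.na(iri)) stop("obo: cannot expand id '", id, "' (unknown prefix)",
                         call. = FALSE)
    iri
  }
  flush_term <- function() {
    if (is.null(cur) || is.null(cur$id)) return()
    iri <- expand_id(cur$id)
    tr <- term_ref(iri, label = cur$name, source_ontology = onto_iri, pm = pm)
    terms[[iri]] <<- tr
    if (identical(stanza, "Term")) {
      classes <<- c(classes, iri)
      for (p in cur$is_a) { sub_c <<- c(sub_c, iri); sub_p <<- c(sub_p, expand_id(p)) }
      for (r in cur$rel) {
        rel_s <<- c(rel_s, iri)
        rel_p <<- c(rel_p, expand_id(r[1]))
        rel_o <<- c(rel_o, expand_id(r[2]))
      }
    } else {
      properties <<- c(properties, iri)
    }
  }

  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^\\[(Term|Typedef|Instance)\\]$", ln)) {
      flush_term()
      stanza <- sub("^\\[(.*)\\]$", "\\1", ln)
      cur <- list(is_a = character(), rel = list())
      next
    }
    if (is.na(stanza)) {
      # header tags; keep the ontology id
      if (startsWith(ln, "ontology:"))
        onto_iri <- paste0("http://purl.org/obo/owl/", trimws(sub("^ontology:", "", ln)))
      next
    }
    colon <- regexpr(":", ln, fixed = TRUE)
    tag <- if (colon > 0L) substr(ln, 1L, colon - 1L) else ""
    if (!grepl("^[A-Za-z_-]+$", tag))
      stop(sprintf("obo: malformed line %d: '%s'", i, ln), call. = FALSE)
    val <- trimws(substr(ln, colon + 1L, nchar(ln)))
    if (tag == "id") cur$id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (tag == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) < 2L)
        stop(sprintf("obo: malformed relationship at line %d", i), call. = FALSE)
      # relation names without a prefix live in the default namespace
      cur$rel[[length(cur$rel) + 1L]] <- c(parts[1], parts[2])
    }
    # other tags ignored
  }
  flush_term()

  new_snapshot(terms, unique(classes), character(), unique(properties),
               data.frame(child = sub_c, parent = sub_p, stringsAsFactors = FALSE),
               data.frame(individual = character(), class = character(),
                          stringsAsFactors = FALSE),
               data.frame(subject = rel_s, property = rel_p, object = rel_o,
                          stringsAsFactors = FALSE),
               onto_iri, pm)
}

# ---- triples -> snapshot --------------------------------------------------

snapshot_from_triples <- function(tri, pm, doc_iri) {
  typ <- tri[tri$p == paste0(RDF, "type") & !tri$o_literal, ]
  is_blank <- function(x) startsWith(x, "_:")

  onto_sub <- typ$s[typ$o == paste0(OWL, "Ontology")]
  onto_iri <- if (length(onto_sub)) onto_sub[1] else doc_iri

  classes <- unique(typ$s[typ$o == paste0(OWL, "Class") & !is_blank(typ$s)])
  individuals <- unique(typ$s[typ$o == paste0(OWL, "NamedIndividual") & !is_blank(typ$s)])
  properties <- unique(typ$s[typ$o %in% paste0(OWL, c("ObjectProperty", "AnnotationProperty")) &
                               !is_blank(typ$s)])

  labels <- tri[tri$p == paste0(RDFS, "label") & tri$o_literal, ]
  label_of <- stats::setNames(labels$o, labels$s)

  sub <- tri[tri$p == paste0(RDFS, "subClassOf") & !tri$o_literal, ]
  named_sub <- sub[!is_blank(sub$o) & !is_blank(sub$s), ]

  # SubClassOf(X, prop some Y) via a blank restriction node
  restr_sub <- sub[is_blank(sub$o) & !is_blank(sub$s), ]
  rel_s <- character(); rel_p <- character(); rel_o <- character()
  if (nrow(restr_sub)) {
    on_prop <- tri[tri$p == paste0(OWL, "onProperty"), ]
    some_of <- tri[tri$p == paste0(OWL, "someValuesFrom"), ]
    for (i in seq_len(nrow(restr_sub))) {
      b <- restr_sub$o[i]
      p <- on_prop$o[on_prop$s == b]
      v <- some_of$o[some_of$s == b]
      if (length(p) == 1L && length(v) == 1L && !is_blank(v)) {
        rel_s <- c(rel_s, restr_sub$s[i]); rel_p <- c(rel_p, p); rel_o <- c(rel_o, v)
      }
    }
  }

  inst <- typ[!is_blank(typ$s) & typ$s %in% individuals &
                typ$o %in% classes, c("s", "o")]

  all_iris <- unique(c(classes, individuals, properties))
  terms <- stats::setNames(lapply(all_iris, function(iri) {
    lab <- if (iri %in% names(label_of)) label_of[[iri]] else NULL
    term_ref(iri, label = lab, source_ontology = onto_iri, pm = pm)
  }), all_iris)

  new_snapshot(terms, classes, individuals, properties,
               data.frame(child = named_sub$s, parent = named_sub$o,
                          stringsAsFactors = FALSE),
               data.frame(individual = inst$s, class = inst$o,
                          stringsAsFactors = FALSE),
               data.frame(subject = rel_s, property = rel_p, object = rel_o,
                          stringsAsFactors = FALSE),
               onto_iri, pm)
}

#' Merge ontology snapshots
#'
#' Terms with the same IRI are kept once (first occurrence wins, which keeps
#' the first-loaded label); edge tables are concatenated.
#'
#' @param ... `ontology_snapshot` objects.
#' @return a merged `ontology_snapshot`.
#' @export
merge_snapshots <- function(...) {
  snaps <- list(...)
  if (length(snaps) == 1L && is.list(snaps[[1]]) &&
      !inherits(snaps[[1]], "ontology_snapshot")) snaps <- snaps[[1]]
  stopifnot(length(snaps) >= 1L)
  terms <- list()
  for (s in snaps) for (iri in names(s$terms))
    if (is.null(terms[[iri]])) terms[[iri]] <- s$terms[[iri]]
  cat_df <- function(f) unique(do.call(rbind, lapply(snaps, `[[`, f)))
  new_snapshot(terms,
               unique(unlist(lapply(snaps, `[[`, "classes"))),
               unique(unlist(lapply(snaps, `[[`, "individuals"))),
               unique(unlist(lapply(snaps, `[[`, "properties"))),
               cat_df("subclass"), cat_df("instance"), cat_df("relationship"),
               snaps[[1]]$ontology_iri, snaps[[1]]$pm)
}

# ---- range specs and validation sets --------------------------------------

#' Describe a term range for a template column
#'
#' @param root a [term_ref], an IRI/CURIE string, or `NULL` for the
#'   whole-ontology sentinel (every class / every individual).
#' @param selector one of `"all-subclasses"`, `"direct-subclasses"`,
#'   `"all-individuals"`, `"direct-individuals"`.
#' @param traversal_relations subset of `c("subclass", "part-of")` traversed
#'   by the `all-subclasses` closure.
#' @param source_ontology optional ontology IRI, documentation only.
#' @return an object of class `range_spec`.
#' @export
range_spec <- function(root = NULL,
                       selector = c("all-subclasses", "direct-subclasses",
                                    "all-individuals", "direct-individuals"),
                       traversal_relations = "subclass",
                       source_ontology = NA_character_) {
  selector <- match.arg(selector)
  stopifnot(all(traversal_relations %in% c("subclass", "part-of")))
  if (selector == "all-subclasses" && length(traversal_relations) == 0L)
    stop("range_spec: all-subclasses needs at least one traversal relation",
         call. = FALSE)
  structure(list(root = root, selector = selector,
                 traversal_relations = traversal_relations,
                 source_ontology = source_ontology),
            class = "range_spec")
}

root_iri <- function(spec, snapshot) {
  r <- spec$root
  if (is.null(r)) return(NULL)
  if (inherits(r, "term_ref")) r <- r$iri
  iri <- if (grepl("://", r, fixed = TRUE)) r else pm_expand(snapshot$pm, r)
  if (is.na(iri) || !iri %in% names(snapshot$terms))
    stop("resolve_range: unknown term '", if (is.na(iri)) r else iri, "'",
         call. = FALSE)
  iri
}

# visited-set depth-first descent; cycles (a node on its own descent path)
# are tolerated and reported once as a warning -- rejoining paths in a
# diamond-shaped hierarchy are normal and stay silent
descend <- function(root, children_of) {
  color <- new.env(parent = emptyenv())  # 1 = on path, 2 = done
  cycle <- FALSE
  visit <- function(x) {
    assign(x, 1L, envir = color)
    for (k in children_of(x)) {
      st <- if (exists(k, envir = color, inherits = FALSE))
        get(k, envir = color) else 0L
      if (st == 0L) visit(k) else if (st == 1L) cycle <<- TRUE
    }
    assign(x, 2L, envir = color)
  }
  visit(root)
  if (cycle) warning("resolve_range: cycle detected in the asserted hierarchy",
                     call. = FALSE)
  setdiff(ls(color), root)
}

#' Resolve a range specification into a validation set
#'
#' `all-subclasses` collects every term reachable from the root by one or
#' more hops over the chosen traversal relations (subclass and/or part-of),
#' excluding the root itself; `direct-subclasses` its one-hop children;
#' the individual selectors work analogously over instance-of edges
#' (`all-individuals` includes individuals of any descendant class).
#' Members are ordered lexicographically by IRI.
#'
#' @param spec a [range_spec].
#' @param snapshot an `ontology_snapshot`.
#' @return an object of class `validation_set` with fields `members`
#'   (list of [term_ref]) and `spec`.
#' @export
resolve_range <- function(spec, snapshot) {
  stopifnot(inherits(spec, "range_spec"), inherits(snapshot, "ontology_snapshot"))
  root <- root_iri(spec, snapshot)
  sub <- snapshot$subclass
  po <- partof_edges(snapshot)
  children_of <- function(x) {
    kids <- character()
    if ("subclass" %in% spec$traversal_relations)
      kids <- c(kids, sub$child[sub$parent == x])
    if ("part-of" %in% spec$traversal_relations)
      kids <- c(kids, po$part[po$whole == x])
    kids
  }
  members <- switch(
    spec$selector,
    "all-subclasses" = if (is.null(root)) snapshot$classes else descend(root, children_of),
    "direct-subclasses" = {
      if (is.null(root)) stop("resolve_range: direct-subclasses needs a root",
                              call. = FALSE)
      unique(children_of(root))
    },
    "all-individuals" = {
      inst <- snapshot$instance
      if (is.null(root)) unique(inst$individual)
      else {
        cls <- c(root, descend(root, children_of))
        unique(inst$individual[inst$class %in% cls])
      }
    },
    "direct-individuals" = {
      inst <- snapshot$instance
      if (is.null(root)) unique(inst$individual)
      else unique(inst$individual[inst$class == root])
    }
  )
  members <- sort(members)
  structure(list(members = lapply(members, function(iri) snapshot$terms[[iri]]),
                 spec = spec),
            class = "validation_set")
}

#' Build a validation set directly from term records
#'
#' Used when reconstructing validations from a workbook's hidden sheet,
#' where no range specification survives.
#'
#' @param terms list of [term_ref].
#' @param spec optional originating [range_spec].
#' @return a `validation_set`.
#' @export
validation_set <- function(terms, spec = NULL) {
  iris <- vapply(terms, `[[`, "", "iri")
  if (anyDuplicated(iris)) {
    keep <- !duplicated(iris)
    terms <- terms[keep]; iris <- iris[keep]
  }
  ord <- order(iris, method = "radix")
  structure(list(members = terms[ord], spec = spec), class = "validation_set")
}

#' @export
print.validation_set <- function(x, ...) {
  cat("<validation_set> ", length(x$members), " terms\n", sep = "")
  invisible(x)
}

#' Find validation-set members by label
#'
#' Comparison is case-insensitive with internal whitespace collapsed, against
#' each member's display text ([label_or_fragment]).
#'
#' @param text query string.
#' @param vset a `validation_set`.
#' @return list of matching [term_ref] (possibly empty).
#' @export
find_by_label <- function(text, vset) {
  stopifnot(inherits(vset, "validation_set"))
  q <- norm_label(text)
  keys <- vapply(vset$members, function(t) norm_label(label_or_fragment(t)), "")
  vset$members[keys == q]
}
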