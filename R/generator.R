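#' Identifier minting policy
#'
#' Fresh identifiers take the form `<base><PREFIX>_<zero-padded counter>`
#' (e.g. `...#KUPO_0001028` with width 7). The policy carries a mutable
#' registry, so the same unknown label always maps to the same minted IRI
#' within one run, and the counter strictly increases. Candidate IRIs that
#' collide with `reserved` (typically the loaded snapshot's IRIs) are
#' skipped.
#'
#' @param base namespace IRI the minted IRIs live in.
#' @param prefix_label CURIE prefix label and local-name stem, e.g. `"kupo"`
#'   mints locals `KUPO_NNNNNNN`.
#' @param width digit count for zero padding.
#' @param next_index first counter value to try.
#' @param reserved character vector of IRIs that must not be minted.
#' @return an object of class `mint_policy` (environment-backed).
#' @examples
#' pol <- mint_policy("http://purl.org/obo/owl/kupo#", "kupo", next_index = 1028)
#' @export
mint_policy <- function(base, prefix_label, width = 7L, next_index = 1L,
                        reserved = character()) {
  stopifnot(nzchar(base), nzchar(prefix_label), width >= 1L, next_index >= 0L)
  env <- new.env(parent = emptyenv())
  env$next_index <- as.integer(next_index)
  env$registry <- list()   # norm label -> term_ref
  env$minted <- list()     # list(label=, term=) in mint order
  env$reserved <- reserved
  structure(list(base = base, prefix_label = prefix_label,
                 width = as.integer(width), env = env),
            class = "mint_policy")
}

mint_one <- function(policy, label) {
  key <- norm_label(label)
  hit <- policy$env$registry[[key]]
  if (!is.null(hit)) return(hit)
  stem <- toupper(policy$prefix_label)
  repeat {
    idx <- policy$env$next_index
    if (idx > 10^policy$width - 1)
      stop("mint: identifier counter exhausted at width ", policy$width,
           call. = FALSE)
    local <- sprintf(paste0(stem, "_%0", policy$width, "d"), idx)
    iri <- paste0(policy$base, local)
    policy$env$next_index <- idx + 1L
    if (!iri %in% policy$env$reserved) break
  }
  term <- term_ref(iri, curie = paste0(policy$prefix_label, ":", local),
                   label = label, source_ontology = policy$base,
                   is_minted = TRUE)
  policy$env$registry[[key]] <- term
  policy$env$minted[[length(policy$env$minted) + 1L]] <-
    list(label = label, term = term)
  term
}

is_placeholder <- function(term) isTRUE(attr(term, "placeholder"))

placeholder_term <- function(raw) {
  t <- term_ref(paste0("urn:ontopop:placeholder:", gsub("\\s+", "-", norm_label(raw))),
                curie = raw, label = raw)
  attr(t, "placeholder") <- TRUE
  t
}

#' Bind a template row to pattern variables
#'
#' For each mapped variable the ordered terms of the row's cell in that
#' column: resolved tokens contribute their [term_ref], unknown tokens a
#' placeholder entry awaiting [mint_unknown], empty cells an empty list.
#'
#' @param tpl an `ontology_template`.
#' @param row_index 1-based row number.
#' @param column_map named character vector, variable name -> column name,
#'   e.g. `c("?cell" = "A", "?anatomyPart" = "C")`.
#' @return named list of [term_ref] lists (a binding).
#' @export
bind_row <- function(tpl, row_index, column_map) {
  stopifnot(inherits(tpl, "ontology_template"),
            row_index >= 1L, row_index <= length(tpl$rows))
  missing_cols <- setdiff(unname(column_map), names(tpl$columns))
  if (length(missing_cols))
    stop("bind_row: column '", missing_cols[1], "' is not in the template",
         call. = FALSE)
  row <- tpl$rows[[row_index]]
  stats::setNames(lapply(unname(column_map), function(cn) {
    cell <- row[[cn]]
    out <- list()
    for (t in cell$tokens) {
      if (t$status == "resolved") out[[length(out) + 1L]] <- t$term
      else if (t$status == "unknown") out[[length(out) + 1L]] <- placeholder_term(t$raw)
    }
    out
  }), names(column_map))
}

#' Replace unknown-term placeholders with minted identifiers
#'
#' Placeholders produced by [bind_row] are swapped for fresh [term_ref]s
#' minted under `policy`; identical labels (case/whitespace-insensitive)
#' reuse the same minted IRI via the policy's registry. Bindings without
#' placeholders are returned unchanged.
#'
#' @param binding a binding from [bind_row].
#' @param policy a [mint_policy].
#' @return the binding with placeholders replaced.
#' @export
mint_unknown <- function(binding, policy) {
  stopifnot(inherits(policy, "mint_policy"))
  lapply(binding, function(vals) {
    lapply(vals, function(t) {
      if (is_placeholder(t)) mint_one(policy, t$label) else t
    })
  })
}

provenance_tag <- function(template_id, row, script_id, timestamp) {
  structure(list(template = template_id, row = as.integer(row),
                 script = script_id, timestamp = timestamp),
            class = "provenance_tag")
}

# name resolver over a snapshot: CURIE/bare-name -> term_ref, trying IRI
# expansion first, then label match (e.g. the bare conjunct `cell` names
# the CTO root by its label)
snapshot_resolver <- function(snapshot, pm) {
  if (is.null(snapshot)) return(NULL)
  labels <- vapply(snapshot$terms, function(t) norm_label(label_or_fragment(t)), "")
  function(name) {
    iri <- if (grepl("://", name, fixed = TRUE)) name else pm_expand(pm, name)
    if (!is.na(iri) && iri %in% names(snapshot$terms))
      return(snapshot$terms[[iri]])
    hit <- which(labels == norm_label(name))
    if (length(hit)) return(snapshot$terms[[hit[1]]])
    NULL
  }
}

#' Generate an ontology from a populated template
#'
#' Runs the full population pipeline: per row, [bind_row], [mint_unknown],
#' then [expand] of every script, tagging each resulting axiom with a
#' provenance annotation (template id, row index, script id, timestamp).
#' Newly minted terms additionally receive a `Declaration` axiom and a
#' label `AnnotationAssertion`. Output is deterministic given the policy's
#' counter and the injected timestamp.
#'
#' @param tpl an `ontology_template`.
#' @param scripts list of `pattern_script` (or a single one).
#' @param column_map named character vector, variable -> column name,
#'   covering the union of the scripts' input variables.
#' @param policy a [mint_policy].
#' @param snapshot optional merged `ontology_snapshot` used to resolve
#'   bare/CURIE names inside the scripts.
#' @param ontology_iri IRI of the generated ontology.
#' @param rows integer vector of row indices to process (default all).
#' @param timestamp fixed-format text stamped into every provenance tag;
#'   injected rather than wall-clock so runs are reproducible.
#' @param pm `prefix_map`.
#' @return an object of class `generated_ontology`: `axioms` (list of
#'   `list(axiom, prov)`), `minted` (label/term pairs), `report` (per-row
#'   axiom counts; rows contributing zero axioms are flagged).
#' @export
generate <- function(tpl, scripts, column_map, policy,
                     snapshot = NULL,
                     ontology_iri = "http://purl.org/ontopop/generated",
                     rows = NULL,
                     timestamp = "1970-01-01T00:00:00Z",
                     pm = default_prefixes()) {
  if (inherits(scripts, "pattern_script")) scripts <- list(scripts)
  needed <- unique(unlist(lapply(scripts, input_variables)))
  unmapped <- setdiff(needed, names(column_map))
  if (length(unmapped))
    stop("generate: no column mapping for variable '", unmapped[1], "'",
         call. = FALSE)
  if (is.null(rows)) rows <- seq_along(tpl$rows)
  resolve <- snapshot_resolver(snapshot, pm)

  axioms <- list()
  seen_minted <- 0L
  report <- list()
  add <- function(ax, prov) axioms[[length(axioms) + 1L]] <<- list(axiom = ax, prov = prov)

  for (i in rows) {
    binding <- tryCatch(
      mint_unknown(bind_row(tpl, i, column_map), policy),
      error = function(e) stop("generate: row ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    # declaration + label annotation for terms minted on this row
    new_minted <- policy$env$minted
    if (length(new_minted) > seen_minted) {
      for (m in new_minted[(seen_minted + 1L):length(new_minted)]) {
        prov <- provenance_tag(tpl$identifier, i, "minting", timestamp)
        add(new_axiom("Declaration", m$term), prov)
        add(new_axiom("AnnotationAssertion", m$term,
                      annotation = list(property = paste0(RDFS, "label"),
                                        value = m$label)), prov)
      }
      seen_minted <- length(new_minted)
    }
    n_row <- 0L
    for (s in scripts) {
      axs <- tryCatch(
        expand(s, binding[intersect(names(binding), input_variables(s))], resolve),
        error = function(e) stop("generate: row ", i, ", script '", s$id, "': ",
                                 conditionMessage(e), call. = FALSE))
      prov <- provenance_tag(tpl$identifier, i, s$id, timestamp)
      for (ax in axs) add(ax, prov)
      n_row <- n_row + length(axs)
    }
    report[[length(report) + 1L]] <- data.frame(row = i, axioms = n_row,
                                                stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, report)
  structure(list(iri = ontology_iri, pm = pm, axioms = axioms,
                 minted = policy$env$minted, report = report),
            class = "generated_ontology")
}

#' @export
print.generated_ontology <- function(x, ...) {
  kinds <- vapply(x$axioms, function(a) a$axiom$kind, "")
  cat("<generated_ontology> ", x$iri, "\n  ",
      sum(kinds %in% c("SubClassOf", "EquivalentTo")), " logical axioms, ",
      length(x$minted), " minted terms\n", sep = "")
  invisible(x)
}

logical_axioms <- function(onto) {
  Filter(function(a) a$axiom$kind %in% c("SubClassOf", "EquivalentTo"),
         onto$axioms)
}

# ---- Manchester syntax rendering ------------------------------------------

manchester_expr <- function(node, pm) {
  switch(node_kind(node),
    op_term = pm_contract(pm, node$term$iri),
    op_named = node$name,
    op_some = paste0(manchester_expr(node$prop, pm), " some ",
                     manchester_expr(node$filler, pm)),
    op_and = paste(vapply(node$children, function(ch) {
      if (node_kind(ch) %in% c("op_some", "op_and"))
        paste0("(", manchester_expr(ch, pm), ")")
      else manchester_expr(ch, pm)
    }, ""), collapse = " and "),
    stop("manchester_expr: unknown node"))
}

#' Render a generated ontology in Manchester syntax
#'
#' One frame per subject, in first-generation order: a `Class:` line, an
#' optional `Annotations:` block (labels of minted terms), an
#' `EquivalentTo:` block, then a `SubClassOf:` block with comma-separated
#' entries. Restrictions render as `prop some filler`; intersections as
#' `A and (B)` with parentheses around complex conjuncts.
#'
#' @param onto a `generated_ontology`.
#' @return a single string.
#' @export
render_manchester <- function(onto) {
  pm <- onto$pm
  out <- character()
  nm <- names(pm)
  for (i in seq_along(pm))
    if (nzchar(nm[i]) && !nm[i] %in% c("rdf", "rdfs", "owl"))
      out <- c(out, paste0("Prefix: ", nm[i], ": <", pm[[i]], ">"))
  out <- c(out, paste0("Ontology: <", onto$iri, ">"), "")

  subjects <- character()
  per <- list()
  for (a in onto$axioms) {
    s <- a$axiom$subject$iri
    if (!s %in% subjects) { subjects <- c(subjects, s); per[[s]] <- list() }
    per[[s]][[length(per[[s]]) + 1L]] <- a$axiom
  }
  for (s in subjects) {
    axs <- per[[s]]
    kinds <- vapply(axs, `[[`, "", "kind")
    out <- c(out, paste0("Class: ", pm_contract(pm, s)))
    labs <- Filter(function(a) a$kind == "AnnotationAssertion" &&
                     a$annotation$property == paste0(RDFS, "label"), axs)
    if (length(labs)) {
      out <- c(out, "    Annotations:")
      out <- c(out, paste0("        rdfs:label \"",
                           vapply(labs, function(a) a$annotation$value, ""),
                           "\"", c(rep(",", length(labs) - 1L), "")))
    }
    for (kind in c("EquivalentTo", "SubClassOf")) {
      sel <- axs[kinds == kind]
      if (length(sel) == 0L) next
      out <- c(out, paste0("    ", kind, ":"))
      entries <- vapply(sel, function(a) manchester_expr(a$object, pm), "")
      out <- c(out, paste0("        ", entries,
                           c(rep(",", length(entries) - 1L), "")))
    }
    out <- c(out, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Write the run report as TSV
#'
#' @param onto a `generated_ontology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(onto, path) {
  utils::write.table(onto$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
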