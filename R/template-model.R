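#' Template columns
#'
#' @param name column name (unique within a template), e.g. `"A"` or a header
#'   word.
#' @param validation optional `validation_set` constraining the column.
#' @param relation_hint free-text note on the intended relationship
#'   (documentation only, e.g. `"part of"`).
#' @return an object of class `column_def`.
#' @export
column_def <- function(name, validation = NULL, relation_hint = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, validation = validation,
                 relation_hint = relation_hint),
            class = "column_def")
}

cell_token <- function(raw, status, term = NULL) {
  structure(list(raw = raw, status = status, term = term), class = "cell_token")
}

new_cell <- function(tokens) structure(list(tokens = tokens), class = "template_cell")

# split on unescaped '|'; '\|' escapes a literal bar inside a label
split_cell <- function(raw) {
  if (is.na(raw) || !nzchar(trimws(raw))) return(character(0))
  pieces <- strsplit(raw, "(?<!\\\\)\\|", perl = TRUE)[[1]]
  trimws(gsub("\\|", "|", pieces, fixed = TRUE))
}

escape_bar <- function(x) gsub("|", "\\|", x, fixed = TRUE)

#' Parse one multi-valued cell
#'
#' The raw text is split on unescaped vertical bars and each trimmed piece is
#' resolved against the column's validation set: first by label, then as a
#' CURIE, then as a full IRI. Pieces that resolve get status `"resolved"`
#' and carry the matched [term_ref]; the rest are `"unknown"` (the red
#' placeholder state). Invalid content is data, never an error. With no
#' validation set, pieces resolve only if they name a term of `snapshot` by
#' CURIE or IRI.
#'
#' @param raw cell text (may be empty or `NA`).
#' @param validation optional `validation_set`.
#' @param snapshot optional `ontology_snapshot` used for CURIE/IRI lookup.
#' @param pm `prefix_map` for CURIE expansion.
#' @return a `template_cell` holding an ordered list of tokens.
#' @export
parse_cell <- function(raw, validation = NULL, snapshot = NULL,
                       pm = default_prefixes()) {
  pieces <- split_cell(if (length(raw)) raw else "")
  lookup_snapshot <- function(piece) {
    if (is.null(snapshot)) return(NULL)
    iri <- if (grepl("://", piece, fixed = TRUE)) piece else pm_expand(pm, piece)
    if (!is.na(iri) && iri %in% names(snapshot$terms)) snapshot$terms[[iri]] else NULL
  }
  tokens <- lapply(pieces, function(piece) {
    term <- NULL
    if (!is.null(validation)) {
      hits <- find_by_label(piece, validation)
      if (length(hits)) term <- hits[[1]]
      if (is.null(term)) {
        # CURIE, then full IRI, still confined to the validation set
        iri <- if (grepl("://", piece, fixed = TRUE)) piece else pm_expand(pm, piece)
        if (!is.na(iri)) {
          m <- vapply(validation$members, `[[`, "", "iri") == iri
          if (any(m)) term <- validation$members[[which(m)[1]]]
        }
      }
    } else {
      term <- lookup_snapshot(piece)
    }
    if (is.null(term)) cell_token(piece, "unknown")
    else cell_token(piece, "resolved", term)
  })
  new_cell(tokens)
}

cell_text <- function(cell) {
  paste(vapply(cell$tokens, function(t) escape_bar(t$raw), ""), collapse = "|")
}

#' Assemble a template
#'
#' @param columns list of [column_def]; names must be unique.
#' @param rows list of rows; each row is a named list/character vector of raw
#'   cell texts keyed by column name (missing entries become empty cells).
#' @param identifier template id recorded in provenance tags.
#' @param snapshot optional `ontology_snapshot` passed to [parse_cell] for
#'   CURIE/IRI resolution in unvalidated columns.
#' @param pm `prefix_map`.
#' @return an object of class `ontology_template`; `rows` holds parsed
#'   `template_cell` objects, one per column per row (1-based row indices in
#'   all reports).
#' @export
template <- function(columns, rows, identifier = "template",
                     snapshot = NULL, pm = default_prefixes()) {
  cnames <- vapply(columns, `[[`, "", "name")
  if (anyDuplicated(cnames)) stop("template: duplicate column names", call. = FALSE)
  parsed <- lapply(rows, function(row) {
    stats::setNames(lapply(cnames, function(cn) {
      raw <- if (cn %in% names(row)) row[[cn]] else ""
      col <- columns[[which(cnames == cn)]]
      parse_cell(as.character(raw), col$validation, snapshot, pm)
    }), cnames)
  })
  structure(list(columns = stats::setNames(columns, cnames), rows = parsed,
                 identifier = identifier),
            class = "ontology_template")
}

#' @export
print.ontology_template <- function(x, ...) {
  cat("<ontology_template> '", x$identifier, "': ",
      length(x$rows), " rows x ", length(x$columns), " columns (",
      paste(names(x$columns), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Auto-complete a partial entry against a validation set
#'
#' Case-insensitive substring matching over member display texts; entries
#' whose display text *starts* with the query rank first, then the remaining
#' substring matches, each group in canonical (IRI-sorted) set order. An
#' empty query matches everything.
#'
#' @param prefix typed text.
#' @param validation a `validation_set`.
#' @param limit maximum number of suggestions (>= 1).
#' @return character vector of display texts, at most `limit` long.
#' @export
autocomplete <- function(prefix, validation, limit = 10L) {
  stopifnot(inherits(validation, "validation_set"), limit >= 1L)
  disp <- vapply(validation$members, label_or_fragment, "")
  q <- norm_label(prefix)
  if (!nzchar(q)) return(utils::head(disp, limit))
  keys <- norm_label(disp)
  starts <- startsWith(keys, q)
  contains <- !starts & grepl(q, keys, fixed = TRUE)
  utils::head(c(disp[starts], disp[contains]), limit)
}

#' Validate every cell of a template
#'
#' @param tpl an `ontology_template`.
#' @return a `validation_report`: `unknown` (data frame row/column/raw, one
#'   line per unknown token) and `counts` (per-column resolved/unknown/empty
#'   cell tallies; a cell counts as unknown if any of its tokens is unknown,
#'   empty if it has no tokens, resolved otherwise).
#' @export
validate_template <- function(tpl) {
  stopifnot(inherits(tpl, "ontology_template"))
  unk <- list()
  cnames <- names(tpl$columns)
  counts <- stats::setNames(
    rep(list(c(resolved = 0L, unknown = 0L, empty = 0L)), length(cnames)), cnames)
  for (i in seq_along(tpl$rows)) {
    for (cn in cnames) {
      cell <- tpl$rows[[i]][[cn]]
      if (length(cell$tokens) == 0L) {
        counts[[cn]]["empty"] <- counts[[cn]]["empty"] + 1L
        next
      }
      bad <- vapply(cell$tokens, function(t) t$status == "unknown", TRUE)
      if (any(bad)) {
        counts[[cn]]["unknown"] <- counts[[cn]]["unknown"] + 1L
        for (t in cell$tokens[bad])
          unk[[length(unk) + 1L]] <- data.frame(row = i, column = cn,
                                                raw = t$raw,
                                                stringsAsFactors = FALSE)
      } else {
        counts[[cn]]["resolved"] <- counts[[cn]]["resolved"] + 1L
      }
    }
  }
  unknown <- if (length(unk)) do.call(rbind, unk) else
    data.frame(row = integer(), column = character(), raw = character(),
               stringsAsFactors = FALSE)
  counts_df <- data.frame(
    column = cnames,
    resolved = vapply(counts, `[[`, 0L, "resolved"),
    unknown = vapply(counts, `[[`, 0L, "unknown"),
    empty = vapply(counts, `[[`, 0L, "empty"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(unknown = unknown, counts = counts_df,
                 template = tpl$identifier, n_rows = length(tpl$rows)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report for '", x$template, "' (", x$n_rows, " rows)\n",
      sep = "")
  for (i in seq_len(nrow(x$counts)))
    cat(sprintf("  column %-12s resolved %3d  unknown %3d  empty %3d\n",
                x$counts$column[i], x$counts$resolved[i],
                x$counts$unknown[i], x$counts$empty[i]))
  if (nrow(x$unknown) == 0L) {
    cat("  all tokens valid\n")
  } else {
    cat("  invalid tokens:\n")
    for (i in seq_len(nrow(x$unknown)))
      cat(sprintf("    row %d column %s: \"%s\"\n", x$unknown$row[i],
                  x$unknown$column[i], x$unknown$raw[i]))
  }
  invisible(x)
}

#' Write a validation report as TSV
#'
#' One line per token with columns `row`, `column`, `raw`, `status`.
#'
#' @param report a `validation_report` produced by [validate_template];
#'   token-level status requires the originating template.
#' @param tpl the template the report came from.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, tpl, path) {
  rows <- list()
  for (i in seq_along(tpl$rows)) {
    for (cn in names(tpl$columns)) {
      for (t in tpl$rows[[i]][[cn]]$tokens)
        rows[[length(rows) + 1L]] <- data.frame(row = i, column = cn,
                                                raw = t$raw, status = t$status,
                                                stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(row = integer(), column = character(), raw = character(),
               status = character(), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
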