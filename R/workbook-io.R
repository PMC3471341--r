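# Template persistence: a plain-text TSV dialect (the canonical round-trip
# surface), Excel workbooks with a hidden validation worksheet, and
# reusable workflow configurations.

HIDDEN_SHEET <- "_ontology_validation"

#' Workbook layout
#'
#' @param data_sheet_name worksheet holding the template grid.
#' @param hidden_sheet_name hidden worksheet holding one record per
#'   validation-set member: the data-sheet cell range the validation covers,
#'   the term's full URI, its label, and the source ontology URI.
#' @return an object of class `workbook_layout`.
#' @export
workbook_layout <- function(data_sheet_name = "Template",
                            hidden_sheet_name = HIDDEN_SHEET) {
  structure(list(data_sheet_name = data_sheet_name,
                 hidden_sheet_name = hidden_sheet_name),
            class = "workbook_layout")
}

# ---- TSV dialect ----------------------------------------------------------

#' Write a template as TSV
#'
#' First row holds the column names; cells join their token raw texts with
#' `|` (literal bars escaped as `\|`).
#'
#' @param tpl an `ontology_template`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_template_tsv <- function(tpl, path) {
  cnames <- names(tpl$columns)
  lines <- paste(cnames, collapse = "\t")
  for (row in tpl$rows)
    lines <- c(lines, paste(vapply(cnames, function(cn) cell_text(row[[cn]]), ""),
                            collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a template from TSV
#'
#' @param path TSV file written by [write_template_tsv] (first row = column
#'   names).
#' @param validations named list of `validation_set` keyed by column name.
#' @param snapshot optional `ontology_snapshot` for CURIE/IRI fallback.
#' @param identifier template id (defaults to the file name).
#' @param pm `prefix_map`.
#' @return an `ontology_template`.
#' @export
read_template_tsv <- function(path, validations = list(), snapshot = NULL,
                              identifier = NULL, pm = default_prefixes()) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("read_template_tsv: empty file", call. = FALSE)
  if (is.null(identifier)) identifier <- basename(path)
  cnames <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  columns <- lapply(cnames, function(cn)
    column_def(cn, validation = validations[[cn]]))
  rows <- lapply(lines[-1], function(ln) {
    vals <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    length(vals) <- length(cnames)
    vals[is.na(vals)] <- ""
    stats::setNames(as.list(vals), cnames)
  })
  template(columns, rows, identifier = identifier, snapshot = snapshot, pm = pm)
}

# ---- XLSX -----------------------------------------------------------------

python_bin <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("write_workbook: no python interpreter found for the xlsx writer",
       call. = FALSE)
}

col_letter <- function(i) {
  out <- ""
  while (i > 0L) {
    out <- paste0(LETTERS[(i - 1L) %% 26L + 1L], out)
    i <- (i - 1L) %/% 26L
  }
  out
}

letter_col <- function(s) {
  chars <- strsplit(toupper(s), "")[[1]]
  Reduce(function(acc, ch) acc * 26L + match(ch, LETTERS), chars, 0L)
}

#' Write a template as an Excel workbook
#'
#' The data sheet holds column names in row 1 and cell display texts below;
#' the hidden sheet holds one record per validation-set member (cell range,
#' term URI, label, source ontology URI); native dropdown validations on the
#' data columns reference the hidden label ranges. The workbook is produced
#' through the openpyxl library.
#'
#' @param tpl an `ontology_template`.
#' @param path output `.xlsx` path.
#' @param layout a [workbook_layout].
#' @return `path`, invisibly.
#' @export
write_workbook <- function(tpl, path, layout = workbook_layout()) {
  cnames <- names(tpl$columns)
  nrows <- length(tpl$rows)
  data_rows <- c(list(as.list(cnames)),
                 lapply(tpl$rows, function(row)
                   lapply(cnames, function(cn) cell_text(row[[cn]]))))

  hidden_rows <- list()
  validations <- list()
  for (ci in seq_along(cnames)) {
    vset <- tpl$columns[[ci]]$validation
    if (is.null(vset) || length(vset$members) == 0L) next
    rng <- paste0(col_letter(ci), "2:", col_letter(ci), max(nrows, 1L) + 1L)
    first <- length(hidden_rows) + 1L
    for (m in vset$members)
      hidden_rows[[length(hidden_rows) + 1L]] <-
        list(rng, m$iri, label_or_fragment(m),
             if (is.na(m$source_ontology)) "" else m$source_ontology)
    validations[[length(validations) + 1L]] <- list(
      sheet = layout$data_sheet_name, range = rng,
      formula = paste0("'", layout$hidden_sheet_name, "'!$C$", first, ":$C$",
                       length(hidden_rows)))
  }

  spec <- list(
    sheets = list(
      list(name = layout$data_sheet_name, hidden = FALSE, rows = data_rows),
      list(name = layout$hidden_sheet_name, hidden = TRUE, rows = hidden_rows)),
    validations = validations)
  spec_file <- tempfile(fileext = ".json")
  on.exit(unlink(spec_file), add = TRUE)
  jsonlite::write_json(spec, spec_file, auto_unbox = TRUE, null = "null")
  helper <- system.file("python", "xlsx_io.py", package = "ontopop")
  status <- system2(python_bin(), c(helper, spec_file, path),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")))
    stop("write_workbook: xlsx writer failed: ",
         paste(status, collapse = "\n"), call. = FALSE)
  invisible(path)
}

#' Read a template from an Excel workbook
#'
#' Validation sets are reconstructed from the hidden worksheet's records and
#' cells re-parsed against them; a bare spreadsheet (no hidden sheet) loads
#' with no validations attached, so every non-empty token is unknown unless
#' it names a snapshot term. Malformed hidden records are skipped with a
#' warning.
#'
#' @param path `.xlsx` path.
#' @param snapshot optional `ontology_snapshot` for CURIE/IRI fallback.
#' @param layout a [workbook_layout].
#' @param identifier template id (defaults to the file name).
#' @param pm `prefix_map`.
#' @return an `ontology_template`.
#' @export
read_workbook <- function(path, snapshot = NULL, layout = workbook_layout(),
                          identifier = NULL, pm = default_prefixes()) {
  if (is.null(identifier)) identifier <- basename(path)
  sheets <- tryCatch(readxl::excel_sheets(path),
                     error = function(e) stop("read_workbook: not a readable workbook: ",
                                              conditionMessage(e), call. = FALSE))
  data_sheet <- setdiff(sheets, layout$hidden_sheet_name)[1]
  grid <- suppressMessages(
    readxl::read_excel(path, sheet = data_sheet, col_names = FALSE,
                       col_types = "text"))
  grid <- as.data.frame(grid, stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) stop("read_workbook: empty data sheet", call. = FALSE)
  cnames <- as.character(unlist(grid[1, ]))
  cnames[is.na(cnames)] <- ""

  validations <- list()
  if (layout$hidden_sheet_name %in% sheets) {
    hid <- suppressMessages(
      readxl::read_excel(path, sheet = layout$hidden_sheet_name,
                         col_names = FALSE, col_types = "text"))
    hid <- as.data.frame(hid, stringsAsFactors = FALSE)
    by_col <- list()
    for (i in seq_len(nrow(hid))) {
      rng <- hid[i, 1]; uri <- if (ncol(hid) >= 2) hid[i, 2] else NA
      lab <- if (ncol(hid) >= 3) hid[i, 3] else NA
      src <- if (ncol(hid) >= 4) hid[i, 4] else NA
      if (is.na(rng) || is.na(uri) || !grepl("^[A-Z]+[0-9]+(:[A-Z]+[0-9]+)?$", rng)) {
        warning("read_workbook: skipping malformed validation record at hidden row ",
                i, call. = FALSE)
        next
      }
      ci <- letter_col(sub("^([A-Z]+).*", "\\1", rng))
      key <- as.character(ci)
      by_col[[key]] <- c(by_col[[key]], list(term_ref(
        uri, label = if (is.na(lab) || !nzchar(lab)) NULL else lab,
        source_ontology = if (is.na(src) || !nzchar(src)) NA_character_ else src,
        pm = pm)))
    }
    for (key in names(by_col)) {
      ci <- as.integer(key)
      if (ci <= length(cnames) && nzchar(cnames[ci]))
        validations[[cnames[ci]]] <- validation_set(by_col[[key]])
    }
  }

  columns <- lapply(seq_along(cnames), function(ci) {
    if (!nzchar(cnames[ci])) return(NULL)
    column_def(cnames[ci], validation = validations[[cnames[ci]]])
  })
  columns <- Filter(Negate(is.null), columns)
  keep <- which(nzchar(cnames))
  rows <- lapply(seq_len(nrow(grid) - 1L) + 1L, function(ri) {
    stats::setNames(lapply(keep, function(ci) {
      v <- grid[ri, ci]
      if (is.na(v)) "" else as.character(v)
    }), cnames[keep])
  })
  template(columns, rows, identifier = identifier, snapshot = snapshot, pm = pm)
}

# ---- workflow configurations ----------------------------------------------

WORKFLOW_VERSION <- 1L

#' Workflow configuration
#'
#' Bundles everything needed to re-run a population workflow: ontology
#' sources, per-column range specifications, pattern script paths, the
#' variable-to-column map, and the minting policy parameters.
#'
#' @param ontologies list of `list(path=, dialect=)`.
#' @param ranges named list (by column name) of `list(root=, selector=,
#'   traversal_relations=)`.
#' @param scripts character vector of pattern script paths.
#' @param variable_map named character vector, variable -> column name.
#' @param mint `list(base=, prefix_label=, width=, next_index=)`.
#' @param identifier workflow id.
#' @return an object of class `workflow_config`.
#' @export
workflow_config <- function(ontologies = list(), ranges = list(),
                            scripts = character(), variable_map = character(),
                            mint = NULL, identifier = "workflow") {
  ranges <- lapply(ranges, function(r) {
    list(root = r$root, selector = r$selector,
         traversal_relations = as.character(unlist(r$traversal_relations)))
  })
  if (!is.null(mint))
    mint <- list(base = mint$base, prefix_label = mint$prefix_label,
                 width = as.integer(mint$width),
                 next_index = as.integer(mint$next_index))
  structure(list(version = WORKFLOW_VERSION, identifier = identifier,
                 ontologies = ontologies, ranges = ranges,
                 scripts = as.character(scripts),
                 variable_map = variable_map, mint = mint),
            class = "workflow_config")
}

#' Save / load a workflow configuration
#'
#' `load_workflow(save_workflow(c))` is structurally equal to `c`. Files
#' with a different format version raise an explicit error.
#'
#' @param config a `workflow_config`.
#' @param path file path.
#' @return `save_workflow`: `path` invisibly; `load_workflow`: the config.
#' @export
save_workflow <- function(config, path) {
  stopifnot(inherits(config, "workflow_config"))
  x <- unclass(config)
  x$variable_map <- as.list(x$variable_map)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_workflow
#' @export
load_workflow <- function(path) {
  if (!file.exists(path))
    stop("load_workflow: no such file '", path, "'", call. = FALSE)
  x <- yaml::read_yaml(path)
  if (is.null(x$version) || x$version != WORKFLOW_VERSION)
    stop("load_workflow: unsupported workflow version '",
         if (is.null(x$version)) "none" else x$version, "'", call. = FALSE)
  vm <- unlist(x$variable_map)
  if (is.null(vm)) vm <- character()
  workflow_config(ontologies = x$ontologies,
                  ranges = x$ranges,
                  scripts = if (is.null(x$scripts)) character() else x$scripts,
                  variable_map = vm,
                  mint = x$mint,
                  identifier = x$identifier)
}
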