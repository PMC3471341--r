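#' Prefix maps: CURIE <-> IRI conversion
#'
#' A prefix map is an ordered named character vector mapping prefix labels to
#' IRI namespaces. The empty-string prefix is the default namespace: local
#' names in that namespace render bare (no colon) in Manchester output.
#'
#' @param ... named namespace strings, e.g. `cell = "http://purl.org/obo/owl/cell#"`.
#'   A `""` name (or the `.default` argument) sets the default namespace.
#' @param .default optional default namespace IRI.
#' @return an object of class `prefix_map`.
#' @examples
#' pm <- prefix_map(pato = "http://purl.org/obo/owl/pato#")
#' pm_expand(pm, "pato:PATO_0001407")
#' @export
prefix_map <- function(..., .default = NULL) {
  ns <- c(...)
  if (!is.null(.default)) ns <- c(ns, stats::setNames(.default, ""))
  if (is.null(ns)) ns <- character(0)
  if (any(!nzchar(ns))) stop("prefix_map: a prefix maps to an empty namespace", call. = FALSE)
  nm <- names(ns)
  if (is.null(nm)) nm <- rep("", length(ns))
  if (anyDuplicated(nm)) stop("prefix_map: duplicate prefix labels", call. = FALSE)
  structure(stats::setNames(as.character(ns), nm), class = "prefix_map")
}

#' Default prefixes for the bundled miniature vocabularies
#'
#' Covers the CURIE prefixes used throughout the worked examples: `cell:`,
#' `cto:`, `ro:`, `kupo:`, `pato:`, `MA:`, `gene_ontology:`, plus the default
#' namespace that holds unprefixed relation names such as `hasNucleation`.
#'
#' @return a `prefix_map`.
#' @export
default_prefixes <- function() {
  prefix_map(
    cell          = "http://purl.org/obo/owl/cell#",
    cto           = "http://purl.org/obo/owl/cto#",
    pato          = "http://purl.org/obo/owl/pato#",
    MA            = "http://purl.org/obo/owl/MA#",
    gene_ontology = "http://purl.org/obo/owl/gene_ontology#",
    ro            = "http://purl.org/obo/owl/ro#",
    kupo          = "http://purl.org/obo/owl/kupo#",
    rdfs          = "http://www.w3.org/2000/01/rdf-schema#",
    owl           = "http://www.w3.org/2002/07/owl#",
    rdf           = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    .default      = "http://purl.org/ontopop/relations#"
  )
}

#' Expand a CURIE to an absolute IRI
#'
#' Strings that are already absolute IRIs (contain `://`) or that use an
#' unknown prefix are returned unchanged with `NA`/unchanged semantics:
#' unknown prefixes yield `NA_character_` so callers can tell the difference.
#'
#' @param pm a `prefix_map`.
#' @param curie `prefix:local` string; a bare name (no colon) expands in the
#'   default namespace when one is set.
#' @return absolute IRI, or `NA_character_` if the prefix is unknown.
#' @export
pm_expand <- function(pm, curie) {
  vapply(curie, function(x) {
    if (is.na(x) || !nzchar(x)) return(NA_character_)
    if (grepl("://", x, fixed = TRUE)) return(x)
    colon <- regexpr(":", x, fixed = TRUE)
    if (colon < 0L) {
      if ("" %in% names(pm)) return(paste0(pm[[which(names(pm) == "")]], x))
      return(NA_character_)
    }
    pfx <- substr(x, 1L, colon - 1L)
    loc <- substr(x, colon + 1L, nchar(x))
    if (!pfx %in% names(pm)) return(NA_character_)
    paste0(pm[[which(names(pm) == pfx)]], loc)
  }, character(1), USE.NAMES = FALSE)
}

#' Contract an IRI to a CURIE
#'
#' The longest matching namespace wins; ties broken by map order. IRIs in the
#' default namespace contract to the bare local name. IRIs matching no
#' namespace are returned unchanged.
#'
#' @param pm a `prefix_map`.
#' @param iri absolute IRI string(s).
#' @return CURIE (or bare local name / unchanged IRI).
#' @export
pm_contract <- function(pm, iri) {
  nms <- names(pm)
  vapply(iri, function(x) {
    if (is.na(x) || !nzchar(x)) return(NA_character_)
    hit <- startsWith(x, unclass(pm))
    if (!any(hit)) return(x)
    lens <- ifelse(hit, nchar(unclass(pm)), -1L)
    best <- which.max(lens)
    local <- substr(x, nchar(pm[[best]]) + 1L, nchar(x))
    if (nms[best] == "") local else paste0(nms[best], ":", local)
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.prefix_map <- function(x, ...) {
  cat("<prefix_map> ", length(x), " namespaces\n", sep = "")
  nm <- ifelse(nzchar(names(x)), names(x), "(default)")
  cat(paste0("  ", format(nm), "  ", unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
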