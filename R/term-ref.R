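#' Ontology term references
#'
#' A `term_ref` records one ontology term: its absolute IRI, CURIE, optional
#' human-readable label, the IRI of the ontology document it came from, and
#' whether it was minted during generation rather than loaded.
#'
#' @param iri absolute IRI (non-empty).
#' @param curie compact IRI; derived from `iri` via `pm` when omitted.
#' @param label optional label text.
#' @param source_ontology IRI of the originating ontology document.
#' @param is_minted logical; `TRUE` for identifiers minted at generation time.
#' @param pm `prefix_map` used to derive `curie` when not supplied.
#' @return an object of class `term_ref`.
#' @examples
#' term_ref("http://purl.org/obo/owl/pato#PATO_0001407", label = "mononucleate")
#' @export
term_ref <- function(iri, curie = NULL, label = NULL, source_ontology = NA_character_,
                     is_minted = FALSE, pm = default_prefixes()) {
  stopifnot(is.character(iri), length(iri) == 1L, nzchar(iri))
  if (is.null(curie)) curie <- pm_contract(pm, iri)
  structure(
    list(iri = iri, curie = curie,
         label = if (is.null(label) || is.na(label[1])) NULL else as.character(label[1]),
         source_ontology = source_ontology, is_minted = isTRUE(is_minted)),
    class = "term_ref"
  )
}

#' @export
print.term_ref <- function(x, ...) {
  cat("<term_ref> ", x$curie,
      if (!is.null(x$label)) paste0(" \"", x$label, "\""),
      if (x$is_minted) " [minted]", "\n", sep = "")
  invisible(x)
}

#' Display text for a term
#'
#' Returns the label when one is present, otherwise the IRI fragment (the
#' text after the last `#` or `/`).
#'
#' @param term a `term_ref`.
#' @return display string.
#' @examples
#' label_or_fragment(term_ref("http://example.org/x#CL_0000113"))
#' @export
label_or_fragment <- function(term) {
  stopifnot(inherits(term, "term_ref"))
  if (!is.null(term$label)) return(term$label)
  iri_fragment(term$iri)
}

iri_fragment <- function(iri) {
  sub(".*[#/]", "", iri)
}

# case-insensitive, internal-whitespace-collapsed comparison key
norm_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}
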