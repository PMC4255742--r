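#' Ontology source references and ontology annotations
#'
#' ISA-Tab encourages ontology annotation of free-text cells: a value cell may
#' be paired with a `Term Source REF` (the short prefix of a declared ontology
#' source) and a `Term Accession Number` (a local identifier or an absolute
#' IRI). Annotations are resolved to absolute IRIs against the source's base.
#' @name annotations
#' @keywords internal
NULL

#' Construct an ontology source reference
#'
#' @param name short prefix string, e.g. `"OBI"`, `"NCBItaxon"` (non-empty).
#' @param file_or_base IRI base used to absolutise local accessions.
#' @param version,description free-text metadata.
#' @return a list of class `ontology_source`.
#' @export
ontology_source <- function(name, file_or_base = "", version = "",
                            description = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(trimws(name)))
  structure(list(name = trimws(name), file_or_base = trimws(file_or_base),
                 version = version, description = description),
            class = "ontology_source")
}

#' Construct an ontology annotation
#'
#' @param text human-readable label.
#' @param source_ref name of an `ontology_source`, or `""`.
#' @param accession local identifier or absolute IRI, or `""`.
#' @param resolved_iri absolute IRI, or `""` when unresolvable.
#' @return a list of class `ontology_annotation`.
#' @export
ontology_annotation <- function(text = "", source_ref = "", accession = "",
                                resolved_iri = "") {
  structure(list(text = text, source_ref = source_ref, accession = accession,
                 resolved_iri = resolved_iri),
            class = "ontology_annotation")
}

is_empty_annotation <- function(x) {
  is.null(x) || (!nzchar(x$text) && !nzchar(x$accession))
}

is_absolute_iri <- function(x) {
  is.character(x) & grepl("^[A-Za-z][A-Za-z0-9+.-]*://", x)
}

#' Resolve a value / term-source / accession cell triple to an annotation
#'
#' An empty value yields an all-empty annotation. An accession that is already
#' an absolute IRI is used as-is; a local accession is absolutised against the
#' matching declared ontology source's base. An unknown source degrades to a
#' literal-only annotation (empty `resolved_iri`), never an error.
#'
#' @param value value cell string (may be empty).
#' @param source `Term Source REF` cell string.
#' @param accession `Term Accession Number` cell string.
#' @param sources list of [ontology_source()] objects declared in the
#'   investigation file.
#' @return an [ontology_annotation()].
#' @examples
#' src <- ontology_source("NCBItaxon", "http://purl.obolibrary.org/obo/NCBITaxon_")
#' resolve_annotation("Homo sapiens", "NCBItaxon", "9606", list(src))
#' @export
resolve_annotation <- function(value, source = "", accession = "",
                               sources = list()) {
  value <- trimws(value %||% "")
  source <- trimws(source %||% "")
  accession <- trimws(accession %||% "")
  if (!nzchar(value) && !nzchar(accession)) {
    return(ontology_annotation())
  }
  resolved <- ""
  if (nzchar(accession)) {
    if (is_absolute_iri(accession)) {
      resolved <- accession
    } else if (nzchar(source)) {
      for (s in sources) {
        if (identical(s$name, source) && nzchar(s$file_or_base)) {
          base <- s$file_or_base
          resolved <- if (is_absolute_iri(accession)) accession
                      else paste0(base, accession)
          break
        }
      }
    }
  }
  ontology_annotation(text = value, source_ref = source,
                      accession = accession, resolved_iri = resolved)
}

#' Parse a `PREFIX:label` qualifier into a category annotation
#'
#' Qualifiers such as `"OBI:organism"` carry an ontology prefix and a label;
#' a qualifier without a colon is all label.
#' @param qualifier qualifier text from a bracketed header.
#' @return an [ontology_annotation()] with `text` = label, `source_ref` =
#'   prefix (possibly empty).
#' @keywords internal
parse_category_qualifier <- function(qualifier) {
  qualifier <- trimws(qualifier)
  m <- regexpr(":", qualifier, fixed = TRUE)
  if (m > 0L) {
    ontology_annotation(text = trimws(substr(qualifier, m + 1L, nchar(qualifier))),
                        source_ref = trimws(substr(qualifier, 1L, m - 1L)))
  } else {
    ontology_annotation(text = qualifier)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
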