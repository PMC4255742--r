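#' Ontology mapping files: typing the ISA syntax
#'
#' The conversion engine is decoupled from any particular semantic framework:
#' delimited mapping files associate ISA syntactic elements with ontology
#' class IRIs (type rows) and with property relations between elements
#' (property rows). Packaged defaults cover an ISA vocabulary, OBI, SIO and
#' PROV-O style mappings; users layer further files on top, later files
#' taking precedence.
#'
#' A type row has three fields -- `isa element, class label, class IRI` --
#' plus an optional fourth context field (`STUDY`, `ASSAY` or `ANY`, default
#' `ANY`) for elements whose meaning depends on the file they appear in
#' (e.g. `Protocol REF`). A property row has seven fields: subject element,
#' subject label, subject IRI (may be empty), property label, property IRI,
#' object label, object (a class IRI or a bracketed ISA element reference).
#' Blank lines and `#` comments are skipped. Files may be tab- or
#' comma-delimited; the delimiter is sniffed per file.
#' @name semantic-mapping
NULL

#' Default ISA vocabulary namespace for fallback IRIs
#' @export
ISA_NS <- "http://purl.org/isaterms/"

sanitize_token <- function(x) {
  x <- gsub("[^A-Za-z0-9]+", "_", trimws(x))
  gsub("^_+|_+$", "", x)
}

#' Parse one mapping file
#'
#' @param path delimited text file (tab or comma; sniffed).
#' @return list with elements of class `type_mapping` / `property_mapping`.
#' @export
parse_mapping_file <- function(path) {
  lines <- read_isa_lines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(list())
  # sniff delimiter on the first retained line
  delim <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[[i]], delim, fixed = TRUE)[[1L]])
    nf <- length(fields)
    if (nf == 3L || (nf == 4L && toupper(fields[4L]) %in%
                     c("STUDY", "ASSAY", "ANY"))) {
      if (!is_absolute_iri(fields[3L])) {
        stop(sprintf("%s:%d: '%s' is not an absolute IRI", basename(path),
                     lineno[i], fields[3L]), call. = FALSE)
      }
      out[[i]] <- structure(list(
        isa_element = fields[1L], class_label = fields[2L],
        class_iri = fields[3L],
        context = if (nf == 4L) toupper(fields[4L]) else "ANY"),
        class = "type_mapping")
    } else if (nf >= 7L) {
      if (!is_absolute_iri(fields[5L])) {
        stop(sprintf("%s:%d: property IRI '%s' is not absolute",
                     basename(path), lineno[i], fields[5L]), call. = FALSE)
      }
      if (nzchar(fields[3L]) && !is_absolute_iri(fields[3L])) {
        stop(sprintf("%s:%d: subject class IRI '%s' is not absolute",
                     basename(path), lineno[i], fields[3L]), call. = FALSE)
      }
      obj <- fields[7L]
      obj_is_element <- !is_absolute_iri(obj)
      if (!obj_is_element && !is_absolute_iri(obj)) {
        stop(sprintf("%s:%d: object '%s' is neither an IRI nor an element",
                     basename(path), lineno[i], obj), call. = FALSE)
      }
      out[[i]] <- structure(list(
        subject_element = fields[1L], subject_label = fields[2L],
        subject_class_iri = fields[3L], property_label = fields[4L],
        property_iri = fields[5L], object_label = fields[6L],
        object = obj, object_is_element = obj_is_element),
        class = "property_mapping")
    } else {
      stop(sprintf("%s:%d: unrecognised mapping row arity (%d fields)",
                   basename(path), lineno[i], nf), call. = FALSE)
    }
  }
  out
}

#' Assemble a mapping set from files
#'
#' Later files take precedence per (element, context). The packaged defaults
#' live under `system.file("extdata", "mappings", package = "isardf")`.
#'
#' @param paths character vector of mapping-file paths, in order of
#'   increasing precedence.
#' @param isa_ns namespace used to mint fallback IRIs for unmapped elements.
#' @return an object of class `mapping_set`.
#' @export
mapping_set <- function(paths = character(), isa_ns = ISA_NS) {
  files <- lapply(paths, parse_mapping_file)
  structure(list(files = files, provenance = basename(paths), isa_ns = isa_ns),
            class = "mapping_set")
}

#' @export
print.mapping_set <- function(x, ...) {
  cat(sprintf("<mapping_set> %d file(s): %s\n", length(x$files),
              paste(x$provenance, collapse = ", ")))
  invisible(x)
}

#' Load a packaged default mapping framework
#'
#' Loads the ISA vocabulary base mapping and, on top of it, the requested
#' framework file (`obi`, `sio` or `provo`), then any user files with higher
#' precedence still.
#'
#' @param framework one of `"isa"`, `"obi"`, `"sio"`, `"provo"`.
#' @param extra_paths user mapping files layered on top, order significant.
#' @inheritParams mapping_set
#' @return a `mapping_set`.
#' @export
default_mappings <- function(framework = c("obi", "isa", "sio", "provo"),
                             extra_paths = character(), isa_ns = ISA_NS) {
  framework <- match.arg(framework)
  dir <- system.file("extdata", "mappings", package = "isardf")
  paths <- file.path(dir, "isa.csv")
  if (framework != "isa") paths <- c(paths, file.path(dir, paste0(framework, ".csv")))
  mapping_set(c(paths, extra_paths), isa_ns = isa_ns)
}

#' Resolve the class IRI of an ISA syntactic element
#'
#' Searches mapping files from last (highest precedence) to first. Within
#' each file an exact (element, context) entry beats an (element, ANY) entry,
#' and a bracket-qualified entry (e.g. `Characteristics[OBI:organism]`)
#' matches before the bare element family name. With no match at all, a
#' fallback IRI is minted in the ISA vocabulary namespace from the element
#' name; the function is total.
#'
#' @param isa_element element string, possibly with a bracket qualifier.
#' @param context `"STUDY"`, `"ASSAY"` or `"ANY"`.
#' @param mappings a `mapping_set`.
#' @return an absolute IRI (single string).
#' @export
resolve_type <- function(isa_element, context = "ANY", mappings) {
  context <- toupper(context)
  bare <- sub("\\[.*$", "", isa_element)
  bare <- trimws(bare)
  candidates <- unique(c(isa_element, if (!identical(bare, isa_element)) bare))
  for (elem in candidates) {
    for (level in c("exact", "any")) {
      for (f in rev(seq_along(mappings$files))) {
        for (m in mappings$files[[f]]) {
          if (!inherits(m, "type_mapping")) next
          if (!identical(tolower(m$isa_element), tolower(elem))) next
          if (level == "exact" && identical(m$context, context)) {
            return(m$class_iri)
          }
          if (level == "any" && identical(m$context, "ANY")) {
            return(m$class_iri)
          }
        }
      }
    }
  }
  paste0(mappings$isa_ns, sanitize_token(isa_element))
}

#' Property mappings applying to a subject element
#'
#' Returns all property rows whose subject matches, in file order (later
#' files append after earlier ones). Element-reference objects are resolved
#' to class IRIs via [resolve_type()].
#'
#' @inheritParams resolve_type
#' @param subject_element element string to match, e.g.
#'   `"Characteristics[OBI:tissue specimen]"`.
#' @return list of `property_mapping` objects, each with `object_class_iri`
#'   filled in.
#' @export
property_edges_for <- function(subject_element, mappings, context = "ANY") {
  out <- list()
  for (f in seq_along(mappings$files)) {
    for (m in mappings$files[[f]]) {
      if (!inherits(m, "property_mapping")) next
      if (!identical(tolower(m$subject_element), tolower(subject_element))) next
      m$object_class_iri <- if (m$object_is_element) {
        resolve_type(m$object, context, mappings)
      } else {
        m$object
      }
      out <- c(out, list(m))
    }
  }
  out
}

# resolve a predicate token ("has member", ...) through the mapping set so
# frameworks can override the vocabulary; falls back to the ISA namespace
resolve_predicate <- function(token, mappings) {
  resolve_type(token, "ANY", mappings)
}
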