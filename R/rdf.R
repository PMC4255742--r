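#' Triple sink, IRI minting and RDF serialisation
#'
#' RDF statements are `<subject, predicate, object>` triples whose subject
#' and predicate are IRIs and whose object is an IRI or a literal. The sink
#' deduplicates statements on insertion, so re-asserting a triple is a
#' no-op. IRIs for individuals are minted under a user-supplied base IRI
#' with the pattern `<base IRI>/<type>/<counter>`, where the counter
#' enumerates individuals of a type in order of creation, starting at 1;
#' an element identity key is minted at most once.
#' @name rdf-layer
NULL

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"
XSD_INTEGER <- "http://www.w3.org/2001/XMLSchema#integer"

# ---- IRI policy ------------------------------------------------------------

#' Create an IRI minting policy
#'
#' @param base_iri absolute IRI; a trailing `/` is appended if missing.
#' @return an environment of class `iri_policy` with per-type counters.
#' @examples
#' pol <- new_iri_policy("http://w3id.org/isa/soapdenovo2/")
#' mint_iri(pol, "isa_dataset", "dataset|soapdenovo2")
#' @export
new_iri_policy <- function(base_iri) {
  if (!is_absolute_iri(base_iri)) {
    stop("base IRI must be absolute: '", base_iri, "'", call. = FALSE)
  }
  if (!endsWith(base_iri, "/")) base_iri <- paste0(base_iri, "/")
  e <- new.env(parent = emptyenv())
  e$base_iri <- base_iri
  e$counters <- new.env(parent = emptyenv())
  e$minted <- new.env(parent = emptyenv())
  class(e) <- "iri_policy"
  e
}

#' Mint (or look up) the IRI of an element
#'
#' The first request for an element key mints `base/type/counter` and
#' increments that type's counter; repeated requests for the same key return
#' the same IRI.
#'
#' @param policy an [new_iri_policy()] object.
#' @param type_name lowercase type token (spaces are turned into `_`).
#' @param element_key identity key of the element (see [element_key()]).
#' @return an absolute IRI.
#' @export
mint_iri <- function(policy, type_name, element_key) {
  stopifnot(inherits(policy, "iri_policy"))
  key <- paste0(type_name, "\x1f", element_key)
  hit <- policy$minted[[key]]
  if (!is.null(hit)) return(hit)
  type_token <- gsub(" ", "_", tolower(trimws(type_name)))
  n <- policy$counters[[type_token]]
  if (is.null(n)) n <- 1L
  iri <- paste0(policy$base_iri, type_token, "/", n)
  policy$counters[[type_token]] <- n + 1L
  policy$minted[[key]] <- iri
  iri
}

# ---- triple sink -----------------------------------------------------------

#' Create an empty triple sink
#' @param named_graph optional named-graph IRI recorded as metadata.
#' @return an environment of class `triple_sink`.
#' @export
triple_sink <- function(named_graph = NULL) {
  e <- new.env(parent = emptyenv())
  e$s <- character(); e$p <- character(); e$o <- character()
  e$literal <- logical(); e$datatype <- character()
  e$seen <- new.env(parent = emptyenv())
  e$named_graph <- named_graph
  e$warnings <- character()
  class(e) <- "triple_sink"
  e
}

#' Add one triple to a sink
#'
#' @param sink a [triple_sink()].
#' @param s,p subject and predicate IRIs (absolute).
#' @param o object IRI, or literal text when `literal = TRUE`.
#' @param literal is the object a literal?
#' @param datatype literal datatype IRI, or `""` for a plain literal.
#' @return `TRUE` if the statement was new, `FALSE` if it was a duplicate.
#' @export
add_triple <- function(sink, s, p, o, literal = FALSE, datatype = "") {
  if (!is_absolute_iri(s) || !is_absolute_iri(p) ||
      (!literal && !is_absolute_iri(o))) {
    stop("triple terms must be absolute IRIs: <", s, "> <", p, "> <", o, ">",
         call. = FALSE)
  }
  key <- paste(s, p, o, literal, datatype, sep = "\x1f")
  if (!is.null(sink$seen[[key]])) return(invisible(FALSE))
  sink$seen[[key]] <- TRUE
  i <- length(sink$s) + 1L
  sink$s[i] <- s; sink$p[i] <- p; sink$o[i] <- o
  sink$literal[i] <- literal; sink$datatype[i] <- datatype
  invisible(TRUE)
}

#' Statements of a sink as a data frame
#' @param sink a [triple_sink()].
#' @return data.frame with columns `subject`, `predicate`, `object`,
#'   `literal`, `datatype`.
#' @export
triples <- function(sink) {
  data.frame(subject = sink$s, predicate = sink$p, object = sink$o,
             literal = sink$literal, datatype = sink$datatype,
             stringsAsFactors = FALSE)
}

#' Number of statements in a sink
#' @param sink a [triple_sink()].
#' @return integer count.
#' @export
n_triples <- function(sink) length(sink$s)

#' @export
print.triple_sink <- function(x, ...) {
  cat(sprintf("<triple_sink> %d statements\n", n_triples(x)))
  invisible(x)
}

# subset helper: rows matching fixed s/p/o (NULL = wildcard)
match_triples <- function(sink, s = NULL, p = NULL, o = NULL) {
  idx <- rep(TRUE, length(sink$s))
  if (!is.null(s)) idx <- idx & sink$s == s
  if (!is.null(p)) idx <- idx & sink$p == p
  if (!is.null(o)) idx <- idx & sink$o == o
  which(idx)
}

# object values for (s, p); literal_only/iri_only filters
objects_of <- function(sink, s = NULL, p = NULL) {
  sink$o[match_triples(sink, s = s, p = p)]
}

label_of <- function(sink, iri) {
  v <- sink$o[match_triples(sink, s = iri, p = RDFS_LABEL)]
  if (length(v)) v[[1L]] else iri
}

# ---- serialisation ---------------------------------------------------------

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

render_object <- function(o, literal, datatype) {
  ifelse(literal,
         ifelse(nzchar(datatype),
                sprintf('"%s"^^<%s>', escape_literal(o), datatype),
                sprintf('"%s"', escape_literal(o))),
         sprintf("<%s>", o))
}

#' Serialise a sink to N-Triples
#'
#' @param sink a [triple_sink()].
#' @param path output file, or `NULL` to return the lines.
#' @param canonical sort lines (byte order) for byte-stable comparison.
#' @return the lines, invisibly when written to a file.
#' @export
write_ntriples <- function(sink, path = NULL, canonical = TRUE) {
  lines <- sprintf("<%s> <%s> %s .", sink$s, sink$p,
                   render_object(sink$o, sink$literal, sink$datatype))
  if (canonical) lines <- sort(lines, method = "radix")
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

#' Serialise a sink to Turtle
#'
#' Emits full IRIs (every N-Triples document is valid Turtle), grouped by
#' subject with predicate-object lists.
#' @inheritParams write_ntriples
#' @export
write_turtle <- function(sink, path = NULL) {
  df <- triples(sink)
  lines <- character()
  for (s in unique(df$subject)) {
    rows <- df[df$subject == s, , drop = FALSE]
    po <- sprintf("    <%s> %s", rows$predicate,
                  render_object(rows$object, rows$literal, rows$datatype))
    lines <- c(lines, sprintf("<%s>", s),
               paste0(po, c(rep(" ;", nrow(rows) - 1L), " .")), "")
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

#' Serialise a sink to RDF/XML
#' @inheritParams write_ntriples
#' @export
write_rdfxml <- function(sink, path = NULL) {
  split_qname <- function(iri) {
    m <- regexpr("[/#][^/#]+$", iri)
    ns <- substr(iri, 1L, m)
    local <- substr(iri, m + 1L, nchar(iri))
    c(ns, local)
  }
  doc <- xml2::xml_new_root(
    "rdf:RDF",
    "xmlns:rdf" = "http://www.w3.org/1999/02/22-rdf-syntax-ns#")
  df <- triples(sink)
  nsmap <- new.env(parent = emptyenv()); nsmap$n <- 0L
  ns_prefix <- function(ns) {
    hit <- nsmap[[ns]]
    if (!is.null(hit)) return(hit)
    nsmap$n <- nsmap$n + 1L
    pfx <- paste0("ns", nsmap$n)
    xml2::xml_set_attr(doc, paste0("xmlns:", pfx), ns)
    nsmap[[ns]] <- pfx
    pfx
  }
  for (s in unique(df$subject)) {
    node <- xml2::xml_add_child(doc, "rdf:Description", "rdf:about" = s)
    rows <- df[df$subject == s, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      qn <- split_qname(rows$predicate[i])
      tag <- paste0(ns_prefix(qn[1L]), ":", qn[2L])
      if (rows$literal[i]) {
        child <- xml2::xml_add_child(node, tag, rows$object[i])
        if (nzchar(rows$datatype[i])) {
          xml2::xml_set_attr(child, "rdf:datatype", rows$datatype[i])
        }
      } else {
        xml2::xml_add_child(node, tag, "rdf:resource" = rows$object[i])
      }
    }
  }
  if (is.null(path)) return(doc)
  xml2::write_xml(doc, path)
  invisible(doc)
}
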