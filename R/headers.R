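#' Column-header vocabulary of ISA-Tab table files
#'
#' Fixed header names are matched case-insensitively; bracket qualifiers
#' (`Characteristics[...]`, `Factor Value[...]`, ...) are preserved verbatim
#' because their text (e.g. an `OBI:organism` category) matters downstream.
#' @keywords internal
#' @name isa-headers
NULL

# exact (case-folded) header name -> kind, for headers without a qualifier
.ISA_EXACT_HEADERS <- c(
  "source name"            = "SOURCE_NAME",
  "sample name"            = "SAMPLE_NAME",
  "extract name"           = "EXTRACT_NAME",
  "labeled extract name"   = "LABELED_EXTRACT_NAME",
  "labelled extract name"  = "LABELED_EXTRACT_NAME",
  "raw data file"          = "RAW_DATA_FILE",
  "derived data file"      = "DERIVED_DATA_FILE",
  "protocol ref"           = "PROTOCOL_REF",
  "term source ref"        = "TERM_SOURCE_REF",
  "term accession number"  = "TERM_ACCESSION_NUMBER",
  "unit"                   = "UNIT",
  "label"                  = "LABEL"
)

# bracketed header families: "<name>[qualifier]"
.ISA_BRACKET_HEADERS <- c(
  "characteristics" = "CHARACTERISTICS",
  "factor value"    = "FACTOR_VALUE",
  "parameter value" = "PARAMETER_VALUE",
  "comment"         = "COMMENT"
)

# material node kinds and data node kinds, used by the graph analyser
.MATERIAL_KINDS <- c("SOURCE_NAME", "SAMPLE_NAME", "EXTRACT_NAME",
                     "LABELED_EXTRACT_NAME")
.DATA_KINDS <- c("RAW_DATA_FILE", "DERIVED_DATA_FILE", "OTHER_DATA_FILE")

#' Recognise an ISA-Tab column header
#'
#' Classifies a header cell into the ISA column vocabulary. Matching on the
#' fixed vocabulary is case-insensitive; the qualifier (text between the first
#' `[` and the last `]`) is returned verbatim. Unknown headers -- including
#' malformed bracket qualifiers such as `"Characteristics["` -- fall back to
#' kind `OTHER`, never an error.
#'
#' @param text header cell text (non-empty after trimming).
#' @param position 0-based column index.
#' @return an object of class `isa_header` with fields `kind`, `qualifier`,
#'   `position` and the original `text`.
#' @examples
#' recognize_header("Characteristics[OBI:organism]", 1)
#' recognize_header("Source Name", 0)
#' @export
recognize_header <- function(text, position = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- trimws(text)
  if (!nzchar(raw)) stop("header text is empty", call. = FALSE)
  folded <- tolower(raw)
  kind <- "OTHER"
  qualifier <- ""

  if (folded %in% names(.ISA_EXACT_HEADERS)) {
    kind <- unname(.ISA_EXACT_HEADERS[[folded]])
  } else {
    open <- regexpr("[", raw, fixed = TRUE)
    close_all <- gregexpr("]", raw, fixed = TRUE)[[1L]]
    close <- close_all[length(close_all)]
    if (open > 0L && close > open) {
      base <- tolower(trimws(substr(raw, 1L, open - 1L)))
      if (base %in% names(.ISA_BRACKET_HEADERS)) {
        kind <- unname(.ISA_BRACKET_HEADERS[[base]])
        qualifier <- substr(raw, open + 1L, close - 1L)
      } else if (base == "unit") {
        kind <- "UNIT"
        qualifier <- substr(raw, open + 1L, close - 1L)
      }
    } else if (grepl(" file$", folded)) {
      # other data-file variants (Array Data File, Image File, ...)
      kind <- "OTHER_DATA_FILE"
    }
  }
  structure(
    list(kind = kind, qualifier = qualifier,
         position = as.integer(position), text = raw),
    class = "isa_header"
  )
}

#' Render a recognised header back to its canonical ISA-Tab spelling
#' @param header an `isa_header`.
#' @return a single string.
#' @keywords internal
render_header <- function(header) {
  kind <- header$kind
  canon <- c(
    SOURCE_NAME = "Source Name", SAMPLE_NAME = "Sample Name",
    EXTRACT_NAME = "Extract Name", LABELED_EXTRACT_NAME = "Labeled Extract Name",
    RAW_DATA_FILE = "Raw Data File", DERIVED_DATA_FILE = "Derived Data File",
    PROTOCOL_REF = "Protocol REF", TERM_SOURCE_REF = "Term Source REF",
    TERM_ACCESSION_NUMBER = "Term Accession Number", UNIT = "Unit",
    LABEL = "Label"
  )
  bracket <- c(CHARACTERISTICS = "Characteristics", FACTOR_VALUE = "Factor Value",
               PARAMETER_VALUE = "Parameter Value", COMMENT = "Comment")
  if (kind %in% names(bracket)) {
    return(paste0(bracket[[kind]], "[", header$qualifier, "]"))
  }
  if (kind == "UNIT" && nzchar(header$qualifier)) {
    return(paste0("Unit[", header$qualifier, "]"))
  }
  if (kind %in% names(canon)) return(unname(canon[[kind]]))
  header$text
}

#' @export
print.isa_header <- function(x, ...) {
  q <- if (nzchar(x$qualifier)) paste0("[", x$qualifier, "]") else ""
  cat(sprintf("<isa_header> %s%s (col %d, %s)\n", x$kind, q, x$position, x$text))
  invisible(x)
}

is_material_kind <- function(kind) kind %in% .MATERIAL_KINDS
is_data_kind <- function(kind) kind %in% .DATA_KINDS
is_node_kind <- function(kind) is_material_kind(kind) || is_data_kind(kind)
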