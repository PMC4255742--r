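#' Read ISA-Tab archives into a faithful in-memory model
#'
#' An ISA-Tab archive consists of one tab-delimited investigation file
#' (`i_*.txt`) that declares ontology sources, studies, factors, protocols and
#' assays, plus the study (`s_*.txt`) and assay (`a_*.txt`) table files it
#' references. The tables encode a directed acyclic graph of material/data
#' nodes and protocol applications, one row per path.
#' @name isatab-io
NULL

# ---- model constructors ----------------------------------------------------

#' @rdname isatab-io
#' @param name factor name (non-empty).
#' @param type an [ontology_annotation()] giving the factor type.
#' @export
factor_definition <- function(name, type = ontology_annotation()) {
  stopifnot(nzchar(trimws(name)))
  structure(list(name = trimws(name), type = type), class = "isa_factor")
}

#' @rdname isatab-io
#' @param parameter_names list of [ontology_annotation()]s for declared
#'   protocol parameters.
#' @export
protocol_definition <- function(name, type = ontology_annotation(),
                                parameter_names = list()) {
  stopifnot(nzchar(trimws(name)))
  structure(list(name = trimws(name), type = type,
                 parameter_names = parameter_names),
            class = "isa_protocol")
}

#' @rdname isatab-io
#' @param identifier,title study identifier and title.
#' @param design_descriptors list of [ontology_annotation()]s.
#' @param factors list of [factor_definition()]s (unique names).
#' @param protocols list of [protocol_definition()]s (unique names).
#' @param study_table an `isa_table` (the `s_*.txt` file).
#' @param assays list of `list(measurement=, technology=, file=, table=)`.
#' @export
isa_study <- function(identifier, title = "", design_descriptors = list(),
                      factors = list(), protocols = list(),
                      study_table = NULL, assays = list()) {
  fn <- vapply(factors, `[[`, "", "name")
  pn <- vapply(protocols, `[[`, "", "name")
  if (anyDuplicated(fn)) stop("duplicate factor names in study ", identifier)
  if (anyDuplicated(pn)) stop("duplicate protocol names in study ", identifier)
  structure(list(identifier = identifier, title = title,
                 design_descriptors = design_descriptors, factors = factors,
                 protocols = protocols, study_table = study_table,
                 assays = assays),
            class = "isa_study")
}

#' @rdname isatab-io
#' @param ontology_sources list of [ontology_source()]s (unique names).
#' @param studies list of [isa_study()] objects (unique identifiers).
#' @export
isa_investigation <- function(identifier = "", title = "",
                              ontology_sources = list(), studies = list()) {
  ids <- vapply(studies, `[[`, "", "identifier")
  if (anyDuplicated(ids)) stop("duplicate study identifiers")
  structure(list(identifier = identifier, title = title,
                 ontology_sources = ontology_sources, studies = studies),
            class = "isa_investigation")
}

#' @export
print.isa_investigation <- function(x, ...) {
  cat(sprintf("<isa_investigation> '%s' (%d ontology sources, %d studies)\n",
              x$identifier, length(x$ontology_sources), length(x$studies)))
  for (s in x$studies) {
    cat(sprintf("  study '%s': %d factors, %d protocols, %d assays, %d rows\n",
                s$identifier, length(s$factors), length(s$protocols),
                length(s$assays),
                if (is.null(s$study_table)) 0L else length(s$study_table$rows)))
  }
  invisible(x)
}

# ---- low-level line handling -----------------------------------------------

# Split one raw line into trimmed cells. Wrapping double quotes are removed
# (embedded tabs inside quotes are not supported).
split_cells <- function(line) {
  cells <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(cells) == 0L) cells <- ""
  cells <- trimws(cells)
  quoted <- grepl('^".*"$', cells)
  cells[quoted] <- trimws(gsub('^"|"$', "", cells[quoted]))
  cells
}

read_isa_lines <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file",
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sub("\r$", "", lines)
}

# ---- table files -----------------------------------------------------------

#' Parse a study or assay table file
#'
#' The first line is the header row; headers are classified with
#' [recognize_header()]. Every data row is padded with empty cells to the
#' header width, trailing blank lines are dropped and cell whitespace is
#' trimmed at both ends. A header-only (or empty) file yields zero rows.
#'
#' @param path path to a tab-delimited table file.
#' @param context `"STUDY"` or `"ASSAY"`.
#' @return an object of class `isa_table` with fields `path`, `context`,
#'   `headers` (list of `isa_header`) and `rows` (list of character vectors).
#' @export
parse_table_file <- function(path, context = c("STUDY", "ASSAY")) {
  context <- match.arg(context)
  lines <- read_isa_lines(path)
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (!length(lines)) {
    return(structure(list(path = basename(path), context = context,
                          headers = list(), rows = list()),
                     class = "isa_table"))
  }
  header_cells <- split_cells(lines[[1L]])
  headers <- lapply(seq_along(header_cells), function(i) {
    recognize_header(header_cells[[i]], position = i - 1L)
  })
  ncol <- length(headers)
  rows <- lapply(lines[-1L], function(line) {
    cells <- split_cells(line)
    length(cells) <- ncol                 # pad short rows
    cells[is.na(cells)] <- ""
    cells[seq_len(ncol)]
  })
  structure(list(path = basename(path), context = context,
                 headers = headers, rows = rows),
            class = "isa_table")
}

#' @export
print.isa_table <- function(x, ...) {
  cat(sprintf("<isa_table> %s (%s): %d columns x %d rows\n",
              x$path, x$context, length(x$headers), length(x$rows)))
  invisible(x)
}

# ---- investigation file ----------------------------------------------------

.INV_SECTIONS <- c("ONTOLOGY SOURCE REFERENCE", "INVESTIGATION",
                   "INVESTIGATION PUBLICATIONS", "INVESTIGATION CONTACTS",
                   "STUDY", "STUDY DESIGN DESCRIPTORS", "STUDY PUBLICATIONS",
                   "STUDY FACTORS", "STUDY ASSAYS", "STUDY PROTOCOLS",
                   "STUDY CONTACTS")

# row-oriented section block -> named list of value vectors
section_fields <- function(lines) {
  fields <- list()
  for (line in lines) {
    cells <- split_cells(line)
    if (!nzchar(cells[[1L]])) next
    fields[[cells[[1L]]]] <- if (length(cells) > 1L) cells[-1L] else character()
  }
  fields
}

field_vec <- function(fields, key, n) {
  v <- fields[[key]] %||% character()
  length(v) <- n
  v[is.na(v)] <- ""
  v
}

# assemble annotations from parallel Name/Type + Term Accession/Source rows
annotation_columns <- function(fields, key, n, sources) {
  vals <- field_vec(fields, key, n)
  acc <- field_vec(fields, paste(key, "Term Accession Number"), n)
  src <- field_vec(fields, paste(key, "Term Source REF"), n)
  lapply(seq_len(n), function(i) resolve_annotation(vals[i], src[i], acc[i], sources))
}

#' Parse an ISA-Tab investigation file (or archive)
#'
#' Accepts the path of an investigation file, of a directory containing one
#' `i_*.txt` file, or of a `.zip` archive. The declared study and assay table
#' files are resolved relative to the investigation file and parsed via
#' [parse_table_file()]; a missing referenced table is a format error.
#' Unknown section labels are preserved as opaque blocks, not errors; if two
#' ontology sources share a name the last declaration wins (with a warning).
#'
#' @param path investigation file, directory, or zip archive.
#' @return an [isa_investigation()] model.
#' @export
parse_investigation <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file",
                               call. = FALSE)
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("isatab_zip_")
    utils::unzip(path, exdir = exdir)
    inner <- list.dirs(exdir, recursive = FALSE)
    path <- if (length(list.files(exdir, pattern = "^i_.*\\.txt$")))
      exdir else inner[[1L]]
  }
  if (dir.exists(path)) {
    cand <- list.files(path, pattern = "^i_.*\\.txt$", full.names = TRUE)
    if (!length(cand)) stop("no investigation file (i_*.txt) in '", path, "'",
                            call. = FALSE)
    path <- cand[[1L]]
  }
  dir <- dirname(path)
  lines <- read_isa_lines(path)

  # split into labelled sections, preserving order
  is_label <- vapply(lines, function(l) {
    trimws(strsplit(l, "\t", fixed = TRUE)[[1L]][1L] %||% "") %in% .INV_SECTIONS
  }, logical(1L), USE.NAMES = FALSE)
  # unknown all-caps first cells are opaque sections: treat as labels too so
  # their bodies do not leak into the previous block
  first_cell <- vapply(lines, function(l)
    trimws(strsplit(l, "\t", fixed = TRUE)[[1L]][1L] %||% ""), "",
    USE.NAMES = FALSE)
  opaque <- !is_label & grepl("^[A-Z][A-Z ]+$", first_cell)
  boundary <- is_label | opaque
  if (!any(boundary)) stop("not an investigation file: no section labels",
                           call. = FALSE)
  idx <- cumsum(boundary)
  sections <- split(lines, idx)
  labels <- vapply(sections, function(b)
    trimws(strsplit(b[[1L]], "\t", fixed = TRUE)[[1L]][1L] %||% ""), "")
  if (!any(labels == "STUDY")) {
    stop("investigation file has no STUDY section", call. = FALSE)
  }

  sources <- list()
  inv_id <- ""; inv_title <- ""
  studies <- list()
  cur <- NULL  # accumulator for the study being assembled

  finish_study <- function(cur) {
    st_table <- NULL
    if (nzchar(cur$file)) {
      fp <- file.path(dir, cur$file)
      if (!file.exists(fp)) stop("study table file '", cur$file,
                                 "' referenced but not found", call. = FALSE)
      st_table <- parse_table_file(fp, "STUDY")
    }
    assays <- lapply(cur$assays, function(a) {
      fp <- file.path(dir, a$file)
      if (!file.exists(fp)) stop("assay table file '", a$file,
                                 "' referenced but not found", call. = FALSE)
      a$table <- parse_table_file(fp, "ASSAY")
      a
    })
    isa_study(identifier = cur$id, title = cur$title,
              design_descriptors = cur$designs, factors = cur$factors,
              protocols = cur$protocols, study_table = st_table,
              assays = assays)
  }

  for (k in seq_along(sections)) {
    label <- labels[[k]]
    body <- sections[[k]][-1L]
    fields <- section_fields(body)
    if (label == "ONTOLOGY SOURCE REFERENCE") {
      n <- length(fields[["Term Source Name"]] %||% character())
      nm <- field_vec(fields, "Term Source Name", n)
      fl <- field_vec(fields, "Term Source File", n)
      vr <- field_vec(fields, "Term Source Version", n)
      de <- field_vec(fields, "Term Source Description", n)
      for (i in seq_len(n)) {
        if (!nzchar(nm[i])) next
        if (nm[i] %in% vapply(sources, `[[`, "", "name")) {
          warning("ontology source '", nm[i], "' declared twice; last wins",
                  call. = FALSE)
          sources <- Filter(function(s) s$name != nm[i], sources)
        }
        sources <- c(sources, list(ontology_source(nm[i], fl[i], vr[i], de[i])))
      }
    } else if (label == "INVESTIGATION") {
      inv_id <- (fields[["Investigation Identifier"]] %||% "")[1L] %||% ""
      inv_title <- (fields[["Investigation Title"]] %||% "")[1L] %||% ""
      if (is.na(inv_id)) inv_id <- ""
      if (is.na(inv_title)) inv_title <- ""
    } else if (label == "STUDY") {
      if (!is.null(cur)) studies <- c(studies, list(finish_study(cur)))
      cur <- list(id = (fields[["Study Identifier"]] %||% "")[1L] %||% "",
                  title = (fields[["Study Title"]] %||% "")[1L] %||% "",
                  file = (fields[["Study File Name"]] %||% "")[1L] %||% "",
                  designs = list(), factors = list(), protocols = list(),
                  assays = list())
      cur$id <- if (is.na(cur$id)) "" else cur$id
      cur$title <- if (is.na(cur$title)) "" else cur$title
      cur$file <- if (is.na(cur$file)) "" else cur$file
    } else if (label == "STUDY DESIGN DESCRIPTORS" && !is.null(cur)) {
      n <- length(fields[["Study Design Type"]] %||% character())
      cur$designs <- Filter(Negate(is_empty_annotation),
                            annotation_columns(fields, "Study Design Type", n,
                                               sources))
    } else if (label == "STUDY FACTORS" && !is.null(cur)) {
      n <- length(fields[["Study Factor Name"]] %||% character())
      nm <- field_vec(fields, "Study Factor Name", n)
      types <- annotation_columns(fields, "Study Factor Type", n, sources)
      for (i in seq_len(n)) {
        if (nzchar(nm[i]))
          cur$factors <- c(cur$factors,
                           list(factor_definition(nm[i], types[[i]])))
      }
    } else if (label == "STUDY PROTOCOLS" && !is.null(cur)) {
      n <- length(fields[["Study Protocol Name"]] %||% character())
      nm <- field_vec(fields, "Study Protocol Name", n)
      types <- annotation_columns(fields, "Study Protocol Type", n, sources)
      pars <- field_vec(fields, "Study Protocol Parameters Name", n)
      for (i in seq_len(n)) {
        if (!nzchar(nm[i])) next
        pnames <- strsplit(pars[i], ";", fixed = TRUE)[[1L]]
        pnames <- trimws(pnames[nzchar(trimws(pnames))])
        cur$protocols <- c(cur$protocols, list(protocol_definition(
          nm[i], types[[i]],
          lapply(pnames, function(p) ontology_annotation(text = p)))))
      }
    } else if (label == "STUDY ASSAYS" && !is.null(cur)) {
      n <- length(fields[["Study Assay File Name"]] %||% character())
      files <- field_vec(fields, "Study Assay File Name", n)
      meas <- annotation_columns(fields, "Study Assay Measurement Type", n,
                                 sources)
      tech <- annotation_columns(fields, "Study Assay Technology Type", n,
                                 sources)
      for (i in seq_len(n)) {
        if (nzchar(files[i]))
          cur$assays <- c(cur$assays, list(list(
            measurement = meas[[i]], technology = tech[[i]],
            file = files[i], table = NULL)))
      }
    }
    # other / opaque sections are preserved implicitly (ignored)
  }
  if (!is.null(cur)) studies <- c(studies, list(finish_study(cur)))
  isa_investigation(identifier = inv_id, title = inv_title,
                    ontology_sources = sources, studies = studies)
}
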