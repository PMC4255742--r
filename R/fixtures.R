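#' Seeded synthetic ISA-Tab archives with machine-readable ground truth
#'
#' The generator emulates the canonical transcription-profiling archive
#' shape: sources transformed into samples in the study table (with factor
#' values realising a configurable balanced or imbalanced group design), and
#' an assay table carrying each sample through a protocol chain
#' (sample -> extract -> labeled extract -> raw data file by default).
#' Ground truth (factors, levels, groups, sizes, balance, node and process
#' counts) is derivable from the specification alone and is written as JSON
#' beside the archive. The same seed always yields byte-identical files.
#' @name fixtures
NULL

#' Specify a synthetic archive
#'
#' @param n_studies number of studies.
#' @param factors named list: factor name -> character vector of levels.
#'   Applied to every study.
#' @param group_size single replicate count per factor-level combination, or
#'   a vector with one size per combination (row-major over
#'   `expand.grid(factors)`); its length must then equal the number of
#'   combinations.
#' @param assay_chain list of steps `list(protocol=, output=)` where output
#'   is one of `"Extract Name"`, `"Labeled Extract Name"`,
#'   `"Raw Data File"`, `"Derived Data File"`; the last step must output a
#'   data file.
#' @param annotate_organism give every source a
#'   `Characteristics[OBI:organism]` = Homo sapiens annotation with
#'   NCBItaxon accession 9606.
#' @param factor_values_in where `Factor Value` columns are written:
#'   `"study"`, `"assay"` or `"both"`.
#' @param seed integer fully determining the archive bytes.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_studies = 1L,
                         factors = list(dose = c("low", "high")),
                         group_size = 3L,
                         assay_chain = list(
                           list(protocol = "extraction",
                                output = "Extract Name"),
                           list(protocol = "labeling",
                                output = "Labeled Extract Name"),
                           list(protocol = "hybridization",
                                output = "Raw Data File")),
                         annotate_organism = TRUE,
                         factor_values_in = c("study", "assay", "both"),
                         seed = 1L) {
  factor_values_in <- match.arg(factor_values_in)
  n_combos <- prod(vapply(factors, length, 0L))
  if (length(group_size) > 1L && length(group_size) != n_combos) {
    stop("group_size list has length ", length(group_size), " but the design",
         " has ", n_combos, " factor-level combinations", call. = FALSE)
  }
  last_out <- assay_chain[[length(assay_chain)]]$output
  if (!grepl("Data File$", last_out)) {
    stop("assay_chain must end in a data-file step", call. = FALSE)
  }
  structure(list(n_studies = as.integer(n_studies), factors = factors,
                 group_size = as.integer(group_size),
                 assay_chain = assay_chain,
                 annotate_organism = isTRUE(annotate_organism),
                 factor_values_in = factor_values_in,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# ground truth derivable from a spec alone, for one study
spec_ground_truth_study <- function(spec, sid) {
  levels <- spec$factors
  combos <- expand.grid(levels, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  n_combos <- nrow(combos)
  sizes <- if (length(spec$group_size) == 1L)
    rep(spec$group_size, n_combos) else spec$group_size
  combo_str <- vapply(seq_len(n_combos), function(j) {
    f <- sort(names(levels))
    paste(sprintf("%s=%s", f, unlist(combos[j, f])), collapse = ";")
  }, "")
  ord <- order(combo_str)
  n_samples <- sum(sizes)
  n_mat_steps <- sum(!grepl("Data File$", vapply(spec$assay_chain,
                                                 `[[`, "", "output")))
  n_data_steps <- length(spec$assay_chain) - n_mat_steps
  list(
    study = sid,
    factors = lapply(levels, function(l) sort(unique(l))),
    level_counts = vapply(levels, function(l) length(unique(l)), 0L),
    groups = stats::setNames(as.list(sizes[ord]), combo_str[ord]),
    n_groups = n_combos,
    min_size = min(sizes), max_size = max(sizes),
    balanced = length(unique(sizes)) == 1L,
    n_samples = n_samples,
    node_counts = list(
      SOURCE = n_samples, SAMPLE = n_samples,
      EXTRACT = if (any(vapply(spec$assay_chain, `[[`, "", "output") ==
                       "Extract Name")) n_samples else 0L,
      LABELED_EXTRACT = if (any(vapply(spec$assay_chain, `[[`, "", "output")
                               == "Labeled Extract Name")) n_samples else 0L,
      DATA = n_data_steps * n_samples),
    process_counts = list(
      MATERIAL_TO_MATERIAL = n_samples * (1L + n_mat_steps),
      MATERIAL_TO_DATA = n_samples * n_data_steps,
      DATA_TO_DATA = 0L))
}

pad_id <- function(prefix, i, n) {
  sprintf("%s%0*d", prefix, max(2L, nchar(as.character(n))), i)
}

#' Generate a synthetic ISA-Tab archive
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return the ground truth (class `isa_ground_truth`), also written as
#'   `ground_truth.json` beside the archive.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # local RNG so callers' random streams are untouched
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  inv_id <- sprintf("INV-%d", spec$seed)
  gt <- list(investigation = inv_id, seed = spec$seed, studies = list())
  tab <- function(...) paste(c(...), collapse = "\t")
  ilines <- c("ONTOLOGY SOURCE REFERENCE")
  if (spec$annotate_organism) {
    ilines <- c(ilines,
      tab("Term Source Name", "NCBItaxon", "OBI"),
      tab("Term Source File", "http://purl.obolibrary.org/obo/NCBITaxon_",
          "http://purl.obolibrary.org/obo/OBI_"),
      tab("Term Source Version", "2014", "2014"),
      tab("Term Source Description", "NCBI taxonomy",
          "Ontology for Biomedical Investigations"))
  } else {
    ilines <- c(ilines, tab("Term Source Name"), tab("Term Source File"))
  }
  ilines <- c(ilines, "INVESTIGATION",
              tab("Investigation Identifier", inv_id),
              tab("Investigation Title",
                  sprintf("Synthetic archive (seed %d)", spec$seed)))

  for (s in seq_len(spec$n_studies)) {
    sid <- sprintf("S%d", s)
    sfile <- sprintf("s_%s.txt", sid)
    afile <- sprintf("a_%s_transcriptome.txt", sid)
    st_gt <- spec_ground_truth_study(spec, sid)

    levels <- spec$factors
    combos <- expand.grid(levels, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    sizes <- if (length(spec$group_size) == 1L)
      rep(spec$group_size, nrow(combos)) else spec$group_size
    n <- sum(sizes)
    sample_combo <- rep(seq_len(nrow(combos)), times = sizes)
    # permute rows so grouping does not depend on generation order
    perm <- sample.int(n)
    sample_combo <- sample_combo[perm]

    src <- vapply(seq_len(n), function(i) pad_id("src", i, n), "")
    sam <- vapply(seq_len(n), function(i) pad_id("sam", i, n), "")

    fv_headers <- sprintf("Factor Value[%s]", names(levels))
    fv_cells <- function(i) {
      vapply(names(levels), function(f)
        as.character(combos[sample_combo[i], f]), "")
    }
    with_fv_study <- spec$factor_values_in %in% c("study", "both")
    with_fv_assay <- spec$factor_values_in %in% c("assay", "both")

    # ---- study table
    head <- c("Source Name",
              if (spec$annotate_organism)
                c("Characteristics[OBI:organism]", "Term Source REF",
                  "Term Accession Number"),
              "Protocol REF", "Sample Name",
              if (with_fv_study) fv_headers)
    srows <- vapply(seq_len(n), function(i) {
      tab(src[i],
          if (spec$annotate_organism) c("Homo sapiens", "NCBItaxon", "9606"),
          "sample collection", sam[i],
          if (with_fv_study) fv_cells(i))
    }, "")
    writeLines(c(tab(head), srows), file.path(out_dir, sfile))

    # ---- assay table
    ahead <- "Sample Name"
    for (step in spec$assay_chain) {
      ahead <- c(ahead, "Protocol REF", step$output)
    }
    if (with_fv_assay) ahead <- c(ahead, fv_headers)
    out_name <- function(i, step_k, output) {
      switch(output,
             "Extract Name" = pad_id("ext", i, n),
             "Labeled Extract Name" = pad_id("lex", i, n),
             sprintf("%s_step%d.dat", sam[i], step_k))
    }
    arows <- vapply(seq_len(n), function(i) {
      cells <- sam[i]
      for (k in seq_along(spec$assay_chain)) {
        step <- spec$assay_chain[[k]]
        cells <- c(cells, step$protocol, out_name(i, k, step$output))
      }
      if (with_fv_assay) cells <- c(cells, fv_cells(i))
      tab(cells)
    }, "")
    writeLines(c(tab(ahead), arows), file.path(out_dir, afile))

    # ---- investigation sections for this study
    protos <- c("sample collection",
                vapply(spec$assay_chain, `[[`, "", "protocol"))
    ilines <- c(ilines, "STUDY",
      tab("Study Identifier", sid),
      tab("Study Title", sprintf("Synthetic study %s", sid)),
      tab("Study File Name", sfile),
      "STUDY DESIGN DESCRIPTORS",
      tab("Study Design Type", "intervention design"),
      "STUDY FACTORS",
      tab("Study Factor Name", names(levels)),
      tab("Study Factor Type", rep("categorical", length(levels))),
      "STUDY ASSAYS",
      tab("Study Assay File Name", afile),
      tab("Study Assay Measurement Type", "transcription profiling"),
      tab("Study Assay Technology Type", "DNA microarray"),
      "STUDY PROTOCOLS",
      tab("Study Protocol Name", protos),
      tab("Study Protocol Type", rep("", length(protos))))
    gt$studies[[sid]] <- st_gt
  }
  writeLines(ilines, file.path(out_dir, "i_investigation.txt"))
  gt <- structure(gt, class = "isa_ground_truth")
  jsonlite::write_json(unclass(gt), file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  gt
}

# ---- brute-force oracle ----------------------------------------------------

#' Recover the design directly from the table cells (oracle)
#'
#' Computes factors, levels, groups, sizes and balance straight from the
#' parsed study and assay tables -- locating `Sample Name` and `Factor
#' Value` columns by header kind and grouping distinct factor-value tuples
#' per sample -- with no experiment-graph or RDF machinery. Serves as the
#' independent oracle for the conversion pipeline.
#'
#' @param archive path accepted by [parse_investigation()].
#' @return a list shaped like the generator's ground truth (class
#'   `isa_ground_truth`).
#' @export
brute_force_design <- function(archive) {
  inv <- parse_investigation(archive)
  gt <- list(investigation = inv$identifier, studies = list())
  for (study in inv$studies) {
    declared <- vapply(study$factors, `[[`, "", "name")
    fv <- list()     # sample -> factor -> level
    node_names <- list()
    scan_table <- function(table) {
      if (is.null(table) || !length(table$headers)) return()
      kinds <- vapply(table$headers, `[[`, "", "kind")
      sam_col <- which(kinds == "SAMPLE_NAME")
      fv_cols <- which(kinds == "FACTOR_VALUE")
      for (row in table$rows) {
        for (ci in which(vapply(kinds, is_node_kind, logical(1L)))) {
          if (nzchar(row[ci])) {
            k <- kinds[ci]
            node_names[[k]] <<- unique(c(node_names[[k]], row[ci]))
          }
        }
        if (!length(sam_col) || !nzchar(row[sam_col[1L]])) next
        sm <- row[sam_col[1L]]
        for (ci in fv_cols) {
          if (!nzchar(row[ci])) next
          f <- table$headers[[ci]]$qualifier
          if (!(f %in% declared)) next
          if (is.null(fv[[sm]])) fv[[sm]] <<- list()
          fv[[sm]][[f]] <<- unique(c(fv[[sm]][[f]], row[ci]))
        }
      }
    }
    scan_table(study$study_table)
    for (a in study$assays) scan_table(a$table)

    levels <- lapply(stats::setNames(declared, declared), function(f) {
      sort(unique(unlist(lapply(fv, function(v) v[[f]]))))
    })
    complete <- names(fv)[vapply(fv, function(v)
      all(declared %in% names(v)) &&
        all(vapply(v, length, 0L) == 1L), logical(1L))]
    combos <- vapply(fv[complete], function(v) {
      f <- sort(declared)
      paste(sprintf("%s=%s", f, unlist(v[f])), collapse = ";")
    }, "")
    sizes <- if (length(combos)) table(combos) else integer()
    groups <- stats::setNames(as.list(as.integer(sizes)), names(sizes))
    gt$studies[[study$identifier]] <- list(
      study = study$identifier,
      factors = levels,
      level_counts = vapply(levels, length, 0L),
      groups = groups,
      n_groups = length(groups),
      min_size = if (length(sizes)) min(sizes) else NA_integer_,
      max_size = if (length(sizes)) max(sizes) else NA_integer_,
      balanced = if (length(sizes)) length(unique(as.integer(sizes))) == 1L
                 else NA,
      n_samples = length(complete),
      node_counts = list(
        SOURCE = length(node_names[["SOURCE_NAME"]]),
        SAMPLE = length(node_names[["SAMPLE_NAME"]]),
        EXTRACT = length(node_names[["EXTRACT_NAME"]]),
        LABELED_EXTRACT = length(node_names[["LABELED_EXTRACT_NAME"]]),
        DATA = length(node_names[["RAW_DATA_FILE"]]) +
               length(node_names[["DERIVED_DATA_FILE"]]) +
               length(node_names[["OTHER_DATA_FILE"]])))
  }
  structure(gt, class = "isa_ground_truth")
}

# ---- writer ----------------------------------------------------------------

render_table_lines <- function(table) {
  head <- paste(vapply(table$headers, render_header, ""), collapse = "\t")
  rows <- vapply(table$rows, paste, "", collapse = "\t")
  c(head, rows)
}

annotation_rows <- function(key, anns) {
  list(paste(c(key, vapply(anns, `[[`, "", "text")), collapse = "\t"),
       paste(c(paste(key, "Term Accession Number"),
               vapply(anns, `[[`, "", "accession")), collapse = "\t"),
       paste(c(paste(key, "Term Source REF"),
               vapply(anns, `[[`, "", "source_ref")), collapse = "\t"))
}

#' Serialise an in-memory investigation model back to ISA-Tab
#'
#' Writes `i_investigation.txt` plus one `s_*.txt` per study and the assay
#' tables, such that re-parsing yields a model equal to the original
#' (round-trip property).
#'
#' @param investigation an [isa_investigation()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_isatab <- function(investigation, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  tabj <- function(...) paste(c(...), collapse = "\t")
  L <- c("ONTOLOGY SOURCE REFERENCE",
         tabj("Term Source Name",
              vapply(investigation$ontology_sources, `[[`, "", "name")),
         tabj("Term Source File",
              vapply(investigation$ontology_sources, `[[`, "", "file_or_base")),
         tabj("Term Source Version",
              vapply(investigation$ontology_sources, `[[`, "", "version")),
         tabj("Term Source Description",
              vapply(investigation$ontology_sources, `[[`, "", "description")),
         "INVESTIGATION",
         tabj("Investigation Identifier", investigation$identifier),
         tabj("Investigation Title", investigation$title))
  for (study in investigation$studies) {
    sfile <- if (!is.null(study$study_table) && nzchar(study$study_table$path))
      study$study_table$path else sprintf("s_%s.txt", study$identifier)
    L <- c(L, "STUDY",
           tabj("Study Identifier", study$identifier),
           tabj("Study Title", study$title),
           tabj("Study File Name",
                if (is.null(study$study_table)) "" else sfile),
           "STUDY DESIGN DESCRIPTORS")
    L <- c(L, unlist(annotation_rows("Study Design Type",
                                     study$design_descriptors)))
    L <- c(L, "STUDY FACTORS",
           tabj("Study Factor Name", vapply(study$factors, `[[`, "", "name")),
           unlist(annotation_rows("Study Factor Type",
                                  lapply(study$factors, `[[`, "type"))))
    L <- c(L, "STUDY ASSAYS",
           tabj("Study Assay File Name",
                vapply(study$assays, `[[`, "", "file")),
           unlist(annotation_rows("Study Assay Measurement Type",
                                  lapply(study$assays, `[[`, "measurement"))),
           unlist(annotation_rows("Study Assay Technology Type",
                                  lapply(study$assays, `[[`, "technology"))))
    L <- c(L, "STUDY PROTOCOLS",
           tabj("Study Protocol Name",
                vapply(study$protocols, `[[`, "", "name")),
           unlist(annotation_rows("Study Protocol Type",
                                  lapply(study$protocols, `[[`, "type"))),
           tabj("Study Protocol Parameters Name",
                vapply(study$protocols, function(p)
                  paste(vapply(p$parameter_names, `[[`, "", "text"),
                        collapse = ";"), "")))
    if (!is.null(study$study_table)) {
      sp <- file.path(out_dir, sfile)
      writeLines(render_table_lines(study$study_table), sp)
      paths <- c(paths, sp)
    }
    for (a in study$assays) {
      ap <- file.path(out_dir, a$file)
      writeLines(render_table_lines(a$table), ap)
      paths <- c(paths, ap)
    }
  }
  ip <- file.path(out_dir, "i_investigation.txt")
  writeLines(L, ip)
  invisible(c(ip, paths))
}

#' Canonical fingerprint of an investigation model (for model equality)
#'
#' Reduces a parsed model to the fields that define it (identifiers,
#' declarations, table headers in canonical spelling, cell contents), so two
#' parses can be compared with `identical()` regardless of incidental
#' attributes.
#' @param investigation an [isa_investigation()].
#' @return a nested list.
#' @export
model_fingerprint <- function(investigation) {
  ann <- function(a) list(a$text, a$source_ref, a$accession)
  tbl <- function(t) {
    if (is.null(t)) return(NULL)
    list(headers = vapply(t$headers, render_header, ""), rows = t$rows)
  }
  list(
    identifier = investigation$identifier,
    title = investigation$title,
    sources = lapply(investigation$ontology_sources, function(s)
      list(s$name, s$file_or_base)),
    studies = lapply(investigation$studies, function(st) list(
      id = st$identifier, title = st$title,
      designs = lapply(st$design_descriptors, ann),
      factors = lapply(st$factors, function(f) list(f$name, ann(f$type))),
      protocols = lapply(st$protocols, function(p)
        list(p$name, ann(p$type),
             vapply(p$parameter_names, `[[`, "", "text"))),
      study_table = tbl(st$study_table),
      assays = lapply(st$assays, function(a)
        list(a$file, ann(a$measurement), ann(a$technology), tbl(a$table))))))
}
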