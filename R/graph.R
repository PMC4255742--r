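#' Recover the directed acyclic experiment graph from ISA-Tab tables
#'
#' Each table row is one path through the experiment DAG: material/data node
#' columns alternate with `Protocol REF` columns, and attribute columns
#' (`Characteristics[...]`, `Parameter Value[...]`, `Unit`, term-source
#' pairs) qualify the nearest annotatable column to their left. Nodes are
#' identified by (kind, name); a protocol application is identified by the
#' combination of its name, parameter values, inputs and outputs, so two rows
#' sharing a protocol name may denote the same or different applications.
#' @name experiment-graph
NULL

# ---- attribute values ------------------------------------------------------

#' @rdname experiment-graph
#' @param category qualifier string of the attribute column (non-empty).
#' @param element_form the full column form, e.g.
#'   `"Characteristics[OBI:organism]"`, used to match property mappings.
#' @param value an [ontology_annotation()] (possibly literal-only).
#' @param unit an [ontology_annotation()] or `NULL`.
#' @export
attribute_value <- function(category, element_form, value, unit = NULL) {
  stopifnot(nzchar(category))
  structure(list(category = category,
                 category_annotation = parse_category_qualifier(category),
                 element_form = element_form, value = value, unit = unit),
            class = "isa_attribute")
}

attr_signature <- function(a) {
  paste(a$category, a$value$text, a$value$resolved_iri,
        if (is.null(a$unit)) "" else a$unit$text, sep = "\x1f")
}

# ---- identity keys ---------------------------------------------------------

material_key <- function(node_type, name) {
  sprintf("material|%s|%s", node_type, name)
}

data_key <- function(data_kind, name) {
  sprintf("data|%s|%s", data_kind, name)
}

canon_params <- function(parameter_values) {
  if (!length(parameter_values)) return("")
  paste(sort(vapply(parameter_values, attr_signature, "")), collapse = ";")
}

process_key <- function(protocol_name, parameter_values, inputs, outputs) {
  sprintf("process|%s|%s|IN:%s|OUT:%s", protocol_name,
          canon_params(parameter_values),
          paste(sort(inputs), collapse = ","),
          paste(sort(outputs), collapse = ","))
}

#' Identity key of a graph element
#'
#' Materials and data files are identified by (kind, name); protocol
#' applications by the tuple (protocol name, canonicalised parameter values,
#' sorted inputs, sorted outputs). Equal keys denote the same individual.
#'
#' @param element a material, data or process node from an `isa_graph`.
#' @return a single string key.
#' @export
element_key <- function(element) {
  switch(class(element)[1L],
    isa_material = material_key(element$node_type, element$name),
    isa_data = data_key(element$data_kind, element$name),
    isa_process = process_key(element$protocol_name, element$parameter_values,
                              element$inputs, element$outputs),
    stop("not a graph element: ", class(element)[1L])
  )
}

new_material <- function(node_type, name) {
  structure(list(name = name, node_type = node_type, characteristics = list(),
                 declared_type_iri = ""),
            class = "isa_material")
}

new_data_node <- function(data_kind, name) {
  structure(list(name = name, data_kind = data_kind), class = "isa_data")
}

# ---- column plan -----------------------------------------------------------

# Precompute, once per table, how each column relates to its neighbours.
column_plan <- function(headers) {
  n <- length(headers)
  kinds <- vapply(headers, `[[`, "", "kind")
  node_cols <- which(vapply(kinds, is_node_kind, logical(1L)))
  proto_cols <- which(kinds == "PROTOCOL_REF")
  nearest_left <- function(i, candidates) {
    left <- candidates[candidates < i]
    if (length(left)) max(left) else NA_integer_
  }
  annotatable <- which(kinds %in% c("CHARACTERISTICS", "FACTOR_VALUE",
                                    "PARAMETER_VALUE", "UNIT"))
  plan <- list(kinds = kinds, node_cols = node_cols, proto_cols = proto_cols,
               owner = rep(NA_integer_, n),       # attribute -> bearer column
               tsr = rep(NA_integer_, n),         # annotatable -> its TSR col
               tan = rep(NA_integer_, n),         # annotatable -> its TAN col
               unit = rep(NA_integer_, n))        # attribute -> its UNIT col
  for (i in seq_len(n)) {
    k <- kinds[i]
    if (k %in% c("CHARACTERISTICS", "LABEL")) {
      plan$owner[i] <- nearest_left(i, node_cols)
    } else if (k == "PARAMETER_VALUE") {
      plan$owner[i] <- nearest_left(i, proto_cols)
    } else if (k == "UNIT") {
      plan$owner[i] <- nearest_left(
        i, which(kinds %in% c("CHARACTERISTICS", "FACTOR_VALUE",
                              "PARAMETER_VALUE")))
      if (!is.na(plan$owner[i])) plan$unit[plan$owner[i]] <- i
    } else if (k %in% c("TERM_SOURCE_REF", "TERM_ACCESSION_NUMBER")) {
      own <- nearest_left(i, annotatable)
      if (!is.na(own)) {
        if (k == "TERM_SOURCE_REF") plan$tsr[own] <- i else plan$tan[own] <- i
      }
    }
  }
  plan
}

# resolve the annotation at annotatable column `col` for one row
cell_annotation <- function(row, col, plan, sources) {
  tsr <- plan$tsr[col]; tan <- plan$tan[col]
  resolve_annotation(row[col],
                     if (is.na(tsr)) "" else row[tsr],
                     if (is.na(tan)) "" else row[tan],
                     sources)
}

cell_attribute <- function(row, col, headers, plan, sources) {
  h <- headers[[col]]
  qualifier <- if (nzchar(h$qualifier)) h$qualifier else h$text
  value <- cell_annotation(row, col, plan, sources)
  unit <- NULL
  ucol <- plan$unit[col]
  if (!is.na(ucol) && nzchar(row[ucol])) {
    unit <- cell_annotation(row, ucol, plan, sources)
  }
  attribute_value(qualifier, render_header(h), value, unit)
}

# ---- graph container -------------------------------------------------------

new_graph <- function(context) {
  structure(list(materials = list(), data = list(), processes = list(),
                 edges = character(), factor_assignments = list(),
                 warnings = character(), context = context),
            class = "isa_graph")
}

#' @export
print.isa_graph <- function(x, ...) {
  cat(sprintf(
    "<isa_graph> (%s) %d materials, %d data files, %d processes, %d edges\n",
    x$context, length(x$materials), length(x$data), length(x$processes),
    length(unique(x$edges))))
  if (length(x$warnings)) {
    cat(" warnings:\n")
    for (w in unique(x$warnings)) cat("  -", w, "\n")
  }
  invisible(x)
}

add_edge <- function(g, from, to) {
  g$edges <- c(g$edges, paste(from, to, sep = "\x1e"))
  g
}

graph_edges <- function(g) {
  e <- unique(g$edges)
  if (!length(e)) return(matrix(character(), ncol = 2L))
  do.call(rbind, strsplit(e, "\x1e", fixed = TRUE))
}

# merge an attribute into a node's characteristic list; duplicate signatures
# collapse, same-category different-value pairs are kept with a warning
absorb_attribute <- function(node, attr) {
  sigs <- vapply(node$characteristics, attr_signature, "")
  s <- attr_signature(attr)
  if (s %in% sigs) return(list(node = node, warning = NULL))
  cats <- vapply(node$characteristics, `[[`, "", "category")
  w <- NULL
  if (attr$category %in% cats) {
    w <- sprintf(
      "material '%s': characteristic '%s' has multiple values ('%s' vs '%s')",
      node$name, attr$category,
      node$characteristics[[match(attr$category, cats)]]$value$text,
      attr$value$text)
  }
  node$characteristics <- c(node$characteristics, list(attr))
  list(node = node, warning = w)
}

# ---- build -----------------------------------------------------------------

.NODE_TYPE_OF <- c(SOURCE_NAME = "SOURCE", SAMPLE_NAME = "SAMPLE",
                   EXTRACT_NAME = "EXTRACT",
                   LABELED_EXTRACT_NAME = "LABELED_EXTRACT")
.DATA_KIND_OF <- c(RAW_DATA_FILE = "RAW", DERIVED_DATA_FILE = "DERIVED",
                   OTHER_DATA_FILE = "OTHER")

#' Build the experiment graph of one table file
#'
#' Segments every row left-to-right into alternating node columns and
#' `Protocol REF` columns. Each maximal run of protocol columns between two
#' non-empty node cells yields one process application per protocol (runs of
#' consecutive protocols chain through minted anonymous intermediate
#' materials). Characteristics attach to the nearest node column on their
#' left, parameter values to the nearest protocol column on their left, and
#' `Factor Value` cells become factor assignments bound to the row's sample.
#' Nodes and processes with equal identity keys merge across rows.
#'
#' @param table an `isa_table` from [parse_table_file()].
#' @param study the owning [isa_study()] (protocol/factor declarations).
#' @param context `"STUDY"` or `"ASSAY"`.
#' @param sources ontology sources used to resolve annotations.
#' @return an object of class `isa_graph`.
#' @export
build_graph <- function(table, study, context = table$context,
                        sources = list()) {
  g <- new_graph(context)
  headers <- table$headers
  if (!length(headers)) return(g)
  plan <- column_plan(headers)
  kinds <- plan$kinds
  declared_factors <- vapply(study$factors, `[[`, "", "name")
  declared_protocols <- vapply(study$protocols, `[[`, "", "name")
  char_cols <- which(kinds %in% c("CHARACTERISTICS", "LABEL"))
  pv_cols <- which(kinds == "PARAMETER_VALUE")
  fv_cols <- which(kinds == "FACTOR_VALUE")

  for (r in seq_along(table$rows)) {
    row <- table$rows[[r]]

    # -- instantiate this row's nodes (empty cells are skipped)
    row_nodes <- list()   # col index (character) -> key
    for (col in plan$node_cols) {
      name <- row[col]
      if (!nzchar(name)) next
      k <- kinds[col]
      if (is_material_kind(k)) {
        key <- material_key(.NODE_TYPE_OF[[k]], name)
        if (is.null(g$materials[[key]])) {
          g$materials[[key]] <- new_material(.NODE_TYPE_OF[[k]], name)
        }
      } else {
        key <- data_key(.DATA_KIND_OF[[k]], name)
        if (is.null(g$data[[key]])) {
          g$data[[key]] <- new_data_node(.DATA_KIND_OF[[k]], name)
        }
      }
      row_nodes[[as.character(col)]] <- key
    }

    # -- characteristics / labels
    for (col in char_cols) {
      own <- plan$owner[col]
      if (is.na(own)) next
      key <- row_nodes[[as.character(own)]]
      if (is.null(key) || !nzchar(row[col])) next
      if (!startsWith(key, "material|")) next
      attr <- cell_attribute(row, col, headers, plan, sources)
      res <- absorb_attribute(g$materials[[key]], attr)
      g$materials[[key]] <- res$node
      if (!is.null(res$warning)) g$warnings <- c(g$warnings, res$warning)
      # an organism characteristic with a resolved term types the material
      if (tolower(attr$category_annotation$text) == "organism" &&
          nzchar(attr$value$resolved_iri)) {
        g$materials[[key]]$declared_type_iri <- attr$value$resolved_iri
      }
    }

    # -- processes: walk node/protocol items in column order
    items_cols <- sort(c(plan$node_cols, plan$proto_cols))
    last_node <- NULL
    pending <- list()   # protocol applications awaiting an output node
    flush_chain <- function(g, from_key, protos, to_key, r) {
      # chain k protocols through k-1 anonymous intermediates
      keys_chain <- from_key
      for (i in seq_along(protos)) {
        out_key <- if (i == length(protos)) to_key else {
          anon <- sprintf("anon_r%03d_c%03d", r, protos[[i]]$col)
          k2 <- material_key("OTHER_MATERIAL", anon)
          if (is.null(g$materials[[k2]]))
            g$materials[[k2]] <- new_material("OTHER_MATERIAL", anon)
          k2
        }
        in_key <- keys_chain[length(keys_chain)]
        p <- structure(list(protocol_name = protos[[i]]$name,
                            parameter_values = protos[[i]]$params,
                            inputs = in_key, outputs = out_key,
                            category = NA_character_, context = context),
                       class = "isa_process")
        pk <- element_key(p)
        if (is.null(g$processes[[pk]])) g$processes[[pk]] <- p
        g <- add_edge(g, in_key, pk)
        g <- add_edge(g, pk, out_key)
        keys_chain <- c(keys_chain, out_key)
      }
      g
    }
    for (col in items_cols) {
      if (kinds[col] == "PROTOCOL_REF") {
        pname <- row[col]
        if (!nzchar(pname)) next
        if (length(declared_protocols) && !(pname %in% declared_protocols)) {
          g$warnings <- c(g$warnings, sprintf(
            "Protocol REF '%s' is not declared in study '%s'",
            pname, study$identifier))
        }
        params <- list()
        for (pc in pv_cols) {
          if (identical(plan$owner[pc], col) && nzchar(row[pc])) {
            params <- c(params,
                        list(cell_attribute(row, pc, headers, plan, sources)))
          }
        }
        pending <- c(pending, list(list(name = pname, params = params,
                                        col = col)))
      } else {
        key <- row_nodes[[as.character(col)]]
        if (is.null(key)) next   # empty node cell: skip, keep protocols pending
        if (length(pending)) {
          if (!is.null(last_node)) {
            g <- flush_chain(g, last_node, pending, key, r)
          } else {
            g$warnings <- c(g$warnings, sprintf(
              "row %d: protocol(s) before any input node were dropped", r))
          }
          pending <- list()
        }
        last_node <- key
      }
    }
    if (length(pending)) {
      g$warnings <- c(g$warnings, sprintf(
        "row %d: trailing protocol(s) without an output node were dropped", r))
    }

    # -- factor values bind to the row's sample (or leftmost material)
    if (length(fv_cols)) {
      anchor <- NULL
      node_keys <- unlist(row_nodes, use.names = FALSE)
      sample_keys <- node_keys[startsWith(node_keys, "material|SAMPLE|")]
      if (length(sample_keys)) {
        anchor <- sample_keys[[1L]]
      } else {
        mat_keys <- node_keys[startsWith(node_keys, "material|")]
        if (length(mat_keys)) anchor <- mat_keys[[1L]]
      }
      if (!is.null(anchor)) {
        for (col in fv_cols) {
          if (!nzchar(row[col])) next
          fname <- headers[[col]]$qualifier
          if (length(declared_factors) && !(fname %in% declared_factors)) {
            g$warnings <- c(g$warnings, sprintf(
              "Factor Value[%s] is not a declared factor of study '%s'",
              fname, study$identifier))
          }
          g$factor_assignments <- c(g$factor_assignments, list(list(
            sample_key = anchor, factor_name = fname,
            level = cell_annotation(row, col, plan, sources),
            origin = paste0(context, "_FILE"))))
        }
      }
    }
  }
  assert_acyclic(g)
  g
}

#' Classify a process by the kinds of its inputs and outputs
#'
#' All-material in and out is a material transformation; material in with at
#' least one data output is data acquisition; all-data in and out is a data
#' transformation. Anything else is `MIXED` (flagged in validation, never
#' silently bucketed).
#' @param process an `isa_process`.
#' @return one of `"MATERIAL_TO_MATERIAL"`, `"MATERIAL_TO_DATA"`,
#'   `"DATA_TO_DATA"`, `"MIXED"`.
#' @export
classify_process <- function(process) {
  mat_in <- startsWith(process$inputs, "material|")
  mat_out <- startsWith(process$outputs, "material|")
  if (all(mat_in) && all(mat_out)) return("MATERIAL_TO_MATERIAL")
  if (all(mat_in) && any(!mat_out)) return("MATERIAL_TO_DATA")
  if (all(!mat_in) && all(!mat_out)) return("DATA_TO_DATA")
  "MIXED"
}

assert_acyclic <- function(g) {
  em <- graph_edges(g)
  if (!nrow(em)) return(invisible(TRUE))
  ig <- igraph::graph_from_edgelist(em, directed = TRUE)
  if (!igraph::is_dag(ig)) {
    stop("experiment graph contains a cycle; ISA-Tab tables must encode a DAG",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Merge a study graph with its assay graphs on shared sample names
#'
#' Sample nodes with equal names unify into one node carrying the union of
#' characteristics (conflicting values for one category produce a validation
#' warning listing both). An assay sample absent from the study table is kept
#' as a dangling sample with a warning. Factor assignments are concatenated
#' with their origins preserved.
#'
#' @param study_graph `isa_graph` built in STUDY context.
#' @param assay_graphs list of `isa_graph`s built in ASSAY context.
#' @return a merged `isa_graph`.
#' @export
merge_study_assay <- function(study_graph, assay_graphs = list()) {
  g <- study_graph
  g$context <- "MERGED"
  study_samples <- names(g$materials)[startsWith(names(g$materials),
                                                 "material|SAMPLE|")]
  for (ag in assay_graphs) {
    for (key in names(ag$materials)) {
      if (is.null(g$materials[[key]])) {
        if (startsWith(key, "material|SAMPLE|") &&
            !(key %in% study_samples)) {
          g$warnings <- c(g$warnings, sprintf(
            "assay sample '%s' does not appear in the study table (dangling)",
            ag$materials[[key]]$name))
        }
        g$materials[[key]] <- ag$materials[[key]]
      } else {
        node <- g$materials[[key]]
        for (attr in ag$materials[[key]]$characteristics) {
          res <- absorb_attribute(node, attr)
          node <- res$node
          if (!is.null(res$warning)) g$warnings <- c(g$warnings, res$warning)
        }
        if (!nzchar(node$declared_type_iri) &&
            nzchar(ag$materials[[key]]$declared_type_iri)) {
          node$declared_type_iri <- ag$materials[[key]]$declared_type_iri
        }
        g$materials[[key]] <- node
      }
    }
    for (key in names(ag$data)) {
      if (is.null(g$data[[key]])) g$data[[key]] <- ag$data[[key]]
    }
    for (key in names(ag$processes)) {
      if (is.null(g$processes[[key]])) g$processes[[key]] <- ag$processes[[key]]
    }
    g$edges <- c(g$edges, ag$edges)
    g$factor_assignments <- c(g$factor_assignments, ag$factor_assignments)
    g$warnings <- c(g$warnings, ag$warnings)
  }
  g$edges <- unique(g$edges)
  assert_acyclic(g)
  g
}

#' Build the merged experiment graph of one study
#'
#' Convenience wrapper: builds the study-table graph and one graph per assay
#' table, then merges them via [merge_study_assay()].
#' @param study an [isa_study()].
#' @param sources ontology sources of the investigation.
#' @return a merged `isa_graph`.
#' @export
build_study_graph <- function(study, sources = list()) {
  sg <- if (is.null(study$study_table)) new_graph("STUDY")
        else build_graph(study$study_table, study, "STUDY", sources)
  ags <- lapply(study$assays, function(a) {
    build_graph(a$table, study, "ASSAY", sources)
  })
  merge_study_assay(sg, ags)
}

#' Export an experiment graph in GraphViz DOT format (for inspection)
#' @param g an `isa_graph`.
#' @param path output file, or `NULL` to return the DOT text.
#' @return the DOT text, invisibly when written to a file.
#' @export
graph_to_dot <- function(g, path = NULL) {
  shape_of <- function(key) {
    if (startsWith(key, "material|")) "ellipse"
    else if (startsWith(key, "data|")) "note"
    else "box"
  }
  label_of <- function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    if (parts[1L] == "process") parts[2L] else parts[3L]
  }
  keys <- c(names(g$materials), names(g$data), names(g$processes))
  ids <- stats::setNames(sprintf("n%d", seq_along(keys)), keys)
  lines <- c("digraph experiment {",
             sprintf('  %s [label="%s", shape=%s];', ids,
                     gsub('"', "'", vapply(keys, label_of, "")),
                     vapply(keys, shape_of, "")))
  em <- graph_edges(g)
  if (nrow(em)) {
    lines <- c(lines, sprintf("  %s -> %s;", ids[em[, 1L]], ids[em[, 2L]]))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
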