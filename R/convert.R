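#' Convert an ISA-Tab investigation to RDF
#'
#' Emits one dataset-level individual, one individual per study, design,
#' factor, factor level, protocol, assay, material node, data node and
#' process, with `rdf:type` triples resolved through the mapping set
#' (context-sensitive for `Protocol REF`), process input/output wiring,
#' characteristic and parameter-value attributes, and inferred study groups
#' with their sizes. Factor levels attach to factors and study groups --
#' never directly to samples -- since factor-value placement varies between
#' study and assay files across designs.
#' @name rdf-conversion
NULL

.MATERIAL_TYPE_NAME <- c(SOURCE = "source", SAMPLE = "sample",
                         EXTRACT = "extract", LABELED_EXTRACT = "labeled_extract",
                         OTHER_MATERIAL = "material")
.MATERIAL_ELEMENT <- c(SOURCE = "Source Name", SAMPLE = "Sample Name",
                       EXTRACT = "Extract Name",
                       LABELED_EXTRACT = "Labeled Extract Name",
                       OTHER_MATERIAL = "Material")
.DATA_ELEMENT <- c(RAW = "Raw Data File", DERIVED = "Derived Data File",
                   OTHER = "Data File")

.PREDICATE_TOKENS <- c("has study", "has assay", "has design", "has factor",
                       "has level", "has group", "has member", "has size",
                       "has input", "has output", "executes protocol",
                       "has characteristic", "has parameter value",
                       "has unit", "has value", "has protocol")

resolve_vocab <- function(mappings) {
  v <- lapply(.PREDICATE_TOKENS, resolve_predicate, mappings = mappings)
  names(v) <- .PREDICATE_TOKENS
  v
}

#' Infer study groups from factor-value assignments
#'
#' Each sample's factor-value vector is the union of its assignments across
#' study and assay origins. Samples whose vector covers every declared factor
#' are grouped by canonical vector equality; one group is produced per
#' distinct vector with size equal to the member count. Samples with a
#' partial vector are excluded (and reported); conflicting levels for one
#' (sample, factor) pair are a hard validation error, since group membership
#' would be ambiguous. With no declared factors the group list is empty.
#'
#' @param graph a merged `isa_graph` (see [build_study_graph()]).
#' @param study the owning [isa_study()].
#' @return list of `study_group` objects: `combination` (named character
#'   vector factor -> level, sorted by factor name), `members` (sorted sample
#'   keys), `size`; with attribute `partial` listing excluded sample keys.
#' @export
infer_study_groups <- function(graph, study) {
  declared <- vapply(study$factors, `[[`, "", "name")
  if (!length(declared)) return(structure(list(), partial = character()))
  by_sample <- list()
  for (a in graph$factor_assignments) {
    if (!(a$factor_name %in% declared)) next
    sk <- a$sample_key
    if (is.null(by_sample[[sk]])) by_sample[[sk]] <- list()
    lev <- unique(c(by_sample[[sk]][[a$factor_name]], a$level$text))
    if (length(lev) > 1L) {
      stop(errorCondition(sprintf(
        "sample '%s' has conflicting levels for factor '%s': %s",
        sk, a$factor_name, paste(sQuote(lev), collapse = " vs ")),
        class = c("isardf_validation_error", "error", "condition")))
    }
    by_sample[[sk]][[a$factor_name]] <- lev
  }
  complete <- vapply(by_sample, function(v) all(declared %in% names(v)),
                     logical(1L))
  partial <- names(by_sample)[!complete]
  combos <- vapply(by_sample[complete], function(v) {
    f <- sort(declared)
    paste(sprintf("%s=%s", f, unlist(v[f])), collapse = ";")
  }, "")
  groups <- list()
  for (cmb in sort(unique(combos))) {
    members <- sort(names(combos)[combos == cmb])
    pairs <- strsplit(strsplit(cmb, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    combination <- stats::setNames(vapply(pairs, `[`, "", 2L),
                                   vapply(pairs, `[`, "", 1L))
    groups <- c(groups, list(structure(
      list(combination = combination, members = members,
           size = length(members)),
      class = "study_group")))
  }
  structure(groups, partial = partial)
}

#' Emit attribute triples for one bearer
#'
#' Each attribute (characteristic or parameter value) becomes a value
#' individual typed by its category class (the category annotation's IRI when
#' the mapping set resolves it, else the generic ISA characteristic class),
#' linked from the bearer with the generic has-characteristic /
#' has-parameter-value property. Ontology-annotated values add a type triple
#' to the value's term IRI; literal-only values get a plain literal; units
#' are linked when present. Property mappings whose subject matches the
#' attribute's column form add their specific extra edge (e.g. a tissue
#' characteristic `part of` the organism characteristic of the same bearer).
#'
#' @param node_iri IRI of the bearer (already minted).
#' @param node_key identity key of the bearer (scopes value individuals).
#' @param attributes list of [attribute_value()]s.
#' @param mappings a `mapping_set`.
#' @param sink a [triple_sink()].
#' @param policy an `iri_policy`.
#' @param predicate_token `"has characteristic"` or `"has parameter value"`.
#' @param context `"STUDY"`, `"ASSAY"` or `"ANY"`.
#' @return invisibly, named character vector element-form -> value IRI.
#' @export
emit_attributes <- function(node_iri, node_key, attributes, mappings, sink,
                            policy, predicate_token = "has characteristic",
                            context = "ANY") {
  vocab <- sink$vocab %||% resolve_vocab(mappings)
  pred <- vocab[[predicate_token]]
  type_name <- if (predicate_token == "has parameter value")
    "parameter_value" else "characteristic_value"
  value_iris <- character()
  for (attr in attributes) {
    vkey <- paste("attrval", node_key, attr_signature(attr), sep = "|")
    viri <- mint_iri(policy, type_name, vkey)
    add_triple(sink, node_iri, pred, viri)
    cat_iri <- resolve_type(attr$element_form, context, mappings)
    add_triple(sink, viri, RDF_TYPE, cat_iri)
    if (nzchar(attr$value$resolved_iri)) {
      add_triple(sink, viri, RDF_TYPE, attr$value$resolved_iri)
      add_triple(sink, viri, RDFS_LABEL, attr$value$text, literal = TRUE)
    } else if (nzchar(attr$value$text)) {
      add_triple(sink, viri, vocab[["has value"]], attr$value$text,
                 literal = TRUE)
    }
    if (!is.null(attr$unit) && !is_empty_annotation(attr$unit)) {
      if (nzchar(attr$unit$resolved_iri)) {
        add_triple(sink, viri, vocab[["has unit"]], attr$unit$resolved_iri)
      } else {
        add_triple(sink, viri, vocab[["has unit"]], attr$unit$text,
                   literal = TRUE)
      }
    }
    value_iris[[attr$element_form]] <- viri
  }
  # second pass: specific property edges between sibling attributes
  for (attr in attributes) {
    edges <- property_edges_for(attr$element_form, mappings, context)
    for (e in edges) {
      subj <- value_iris[[attr$element_form]]
      if (nzchar(e$subject_class_iri)) {
        add_triple(sink, subj, RDF_TYPE, e$subject_class_iri)
      }
      if (e$object_is_element) {
        obj <- value_iris[[e$object]]
        if (is.null(obj) || is.na(obj)) {
          sink$warnings <- c(sink$warnings, sprintf(
            "property mapping '%s': no sibling attribute '%s' on bearer '%s'",
            e$property_label, e$object, node_key))
          next
        }
        add_triple(sink, subj, e$property_iri, obj)
      } else {
        add_triple(sink, subj, e$property_iri, e$object)
      }
    }
  }
  invisible(value_iris)
}

#' Convert an investigation (plus its experiment graphs) to a triple sink
#'
#' @param investigation an [isa_investigation()].
#' @param mappings a `mapping_set`; defaults to the packaged OBI framework.
#' @param policy an `iri_policy`; required (carries the base IRI).
#' @param graphs optional list of merged `isa_graph`s, one per study in
#'   order; built with [build_study_graph()] when omitted.
#' @return a [triple_sink()]; inferred groups are attached as
#'   `sink$study_groups` (named by study identifier) and upstream warnings
#'   as `sink$warnings`.
#' @export
convert_to_rdf <- function(investigation, mappings = default_mappings("obi"),
                           policy, graphs = NULL) {
  stopifnot(inherits(investigation, "isa_investigation"),
            inherits(mappings, "mapping_set"), inherits(policy, "iri_policy"))
  if (is.null(graphs)) {
    graphs <- lapply(investigation$studies, build_study_graph,
                     sources = investigation$ontology_sources)
  }
  stopifnot(length(graphs) == length(investigation$studies))
  sink <- triple_sink()
  vocab <- resolve_vocab(mappings)
  sink$vocab <- vocab
  sink$balanced_class <- resolve_type("balanced design", "ANY", mappings)
  sink$study_groups <- list()

  ds_iri <- mint_iri(policy, "isa_dataset",
                     paste0("dataset|", investigation$identifier))
  add_triple(sink, ds_iri, RDF_TYPE, resolve_type("Investigation", "ANY",
                                                  mappings))
  if (nzchar(investigation$identifier)) {
    add_triple(sink, ds_iri, RDFS_LABEL, investigation$identifier,
               literal = TRUE)
  }

  for (si in seq_along(investigation$studies)) {
    study <- investigation$studies[[si]]
    graph <- graphs[[si]]
    sink$warnings <- c(sink$warnings, graph$warnings)
    sid <- study$identifier
    st_iri <- mint_iri(policy, "study", paste0("study|", sid))
    add_triple(sink, st_iri, RDF_TYPE, resolve_type("Study", "ANY", mappings))
    add_triple(sink, st_iri, RDFS_LABEL, sid, literal = TRUE)
    add_triple(sink, ds_iri, vocab[["has study"]], st_iri)

    # study design individual (the balanced-design annotation target)
    de_iri <- mint_iri(policy, "study_design", paste0("design|", sid))
    dtypes <- vapply(study$design_descriptors, `[[`, "", "resolved_iri")
    dtypes <- dtypes[nzchar(dtypes)]
    if (!length(dtypes)) dtypes <- resolve_type("Study Design", "ANY", mappings)
    for (ti in dtypes) add_triple(sink, de_iri, RDF_TYPE, ti)
    dl <- vapply(study$design_descriptors, `[[`, "", "text")
    dl <- dl[nzchar(dl)]
    add_triple(sink, de_iri, RDFS_LABEL,
               if (length(dl)) dl[[1L]] else paste(sid, "design"),
               literal = TRUE)
    add_triple(sink, st_iri, vocab[["has design"]], de_iri)

    # factors
    factor_iris <- character()
    for (fd in study$factors) {
      f_iri <- mint_iri(policy, "study_factor",
                        paste("factor", sid, fd$name, sep = "|"))
      ft <- if (nzchar(fd$type$resolved_iri)) fd$type$resolved_iri
            else resolve_type("Study Factor", "ANY", mappings)
      add_triple(sink, f_iri, RDF_TYPE, ft)
      add_triple(sink, f_iri, RDFS_LABEL, fd$name, literal = TRUE)
      add_triple(sink, st_iri, vocab[["has factor"]], f_iri)
      factor_iris[[fd$name]] <- f_iri
    }

    # factor levels: distinct assigned levels per declared factor, attached
    # to the factor (never to samples)
    level_iris <- list()
    declared <- names(factor_iris)
    for (fname in declared) level_iris[[fname]] <- character()
    lv_tab <- list()
    for (a in graph$factor_assignments) {
      if (!(a$factor_name %in% declared)) next
      k <- paste(a$factor_name, a$level$text, sep = "\x1f")
      if (is.null(lv_tab[[k]])) lv_tab[[k]] <- a$level
    }
    for (fname in declared) {
      texts <- sort(vapply(
        lv_tab[startsWith(names(lv_tab), paste0(fname, "\x1f"))],
        `[[`, "", "text"))
      for (lvtext in texts) {
        lv <- lv_tab[[paste(fname, lvtext, sep = "\x1f")]]
        l_iri <- mint_iri(policy, "factor_value",
                          paste("fv", sid, fname, lvtext, sep = "|"))
        lt <- if (nzchar(lv$resolved_iri)) lv$resolved_iri
              else resolve_type("Factor Value", "ANY", mappings)
        add_triple(sink, l_iri, RDF_TYPE, lt)
        add_triple(sink, l_iri, RDFS_LABEL, lvtext, literal = TRUE)
        add_triple(sink, factor_iris[[fname]], vocab[["has level"]], l_iri)
        level_iris[[fname]][[lvtext]] <- l_iri
      }
    }

    # protocol definitions
    protocol_iris <- character()
    for (pd in study$protocols) {
      p_iri <- mint_iri(policy, "protocol",
                        paste("protocol", sid, pd$name, sep = "|"))
      pt <- if (nzchar(pd$type$resolved_iri)) pd$type$resolved_iri
            else resolve_type("Protocol", "ANY", mappings)
      add_triple(sink, p_iri, RDF_TYPE, pt)
      add_triple(sink, p_iri, RDFS_LABEL, pd$name, literal = TRUE)
      add_triple(sink, st_iri, vocab[["has protocol"]], p_iri)
      protocol_iris[[pd$name]] <- p_iri
    }

    # assays
    for (a in study$assays) {
      a_iri <- mint_iri(policy, "assay", paste("assay", sid, a$file, sep = "|"))
      add_triple(sink, a_iri, RDF_TYPE,
                 resolve_type("Study Assay", "ANY", mappings))
      add_triple(sink, a_iri, RDFS_LABEL,
                 if (nzchar(a$measurement$text)) a$measurement$text else a$file,
                 literal = TRUE)
      add_triple(sink, st_iri, vocab[["has assay"]], a_iri)
    }

    # materials (insertion order: study table row-major, then assays)
    node_iris <- character()
    for (key in names(graph$materials)) {
      node <- graph$materials[[key]]
      m_iri <- mint_iri(policy, .MATERIAL_TYPE_NAME[[node$node_type]], key)
      node_iris[[key]] <- m_iri
      add_triple(sink, m_iri, RDF_TYPE,
                 resolve_type(.MATERIAL_ELEMENT[[node$node_type]], "ANY",
                              mappings))
      if (nzchar(node$declared_type_iri)) {
        add_triple(sink, m_iri, RDF_TYPE, node$declared_type_iri)
      }
      add_triple(sink, m_iri, RDFS_LABEL, node$name, literal = TRUE)
      emit_attributes(m_iri, key, node$characteristics, mappings, sink,
                      policy, "has characteristic", "ANY")
    }
    for (key in names(graph$data)) {
      node <- graph$data[[key]]
      d_iri <- mint_iri(policy, "data_file", key)
      node_iris[[key]] <- d_iri
      add_triple(sink, d_iri, RDF_TYPE,
                 resolve_type(.DATA_ELEMENT[[node$data_kind]], "ANY", mappings))
      add_triple(sink, d_iri, RDFS_LABEL, node$name, literal = TRUE)
    }

    # processes, typed by the context they occurred in
    for (key in names(graph$processes)) {
      proc <- graph$processes[[key]]
      p_iri <- mint_iri(policy, "process", key)
      add_triple(sink, p_iri, RDF_TYPE,
                 resolve_type("Protocol REF", proc$context, mappings))
      add_triple(sink, p_iri, RDFS_LABEL, proc$protocol_name, literal = TRUE)
      for (ik in proc$inputs) {
        add_triple(sink, p_iri, vocab[["has input"]], node_iris[[ik]])
      }
      for (ok in proc$outputs) {
        add_triple(sink, p_iri, vocab[["has output"]], node_iris[[ok]])
      }
      pd_iri <- protocol_iris[[proc$protocol_name]]
      if (is.null(pd_iri) || is.na(pd_iri)) {
        pd_iri <- mint_iri(policy, "protocol",
                           paste("protocol", sid, proc$protocol_name,
                                 sep = "|"))
        add_triple(sink, pd_iri, RDF_TYPE,
                   resolve_type("Protocol", "ANY", mappings))
        add_triple(sink, pd_iri, RDFS_LABEL, proc$protocol_name,
                   literal = TRUE)
        protocol_iris[[proc$protocol_name]] <- pd_iri
      }
      add_triple(sink, p_iri, vocab[["executes protocol"]], pd_iri)
      emit_attributes(p_iri, key, proc$parameter_values, mappings, sink,
                      policy, "has parameter value", proc$context)
    }

    # inferred study groups with sizes
    groups <- infer_study_groups(graph, study)
    sink$study_groups[[sid]] <- groups
    partial <- attr(groups, "partial")
    if (length(partial)) {
      sink$warnings <- c(sink$warnings, sprintf(
        "study '%s': %d sample(s) with partial factor vectors excluded from grouping: %s",
        sid, length(partial), paste(partial, collapse = ", ")))
    }
    for (grp in groups) {
      cmb <- paste(sprintf("%s=%s", names(grp$combination), grp$combination),
                   collapse = ";")
      g_iri <- mint_iri(policy, "study_group",
                        paste("group", sid, cmb, sep = "|"))
      add_triple(sink, g_iri, RDF_TYPE,
                 resolve_type("Study Group", "ANY", mappings))
      add_triple(sink, g_iri, RDFS_LABEL, cmb, literal = TRUE)
      add_triple(sink, st_iri, vocab[["has group"]], g_iri)
      add_triple(sink, g_iri, vocab[["has size"]], as.character(grp$size),
                 literal = TRUE, datatype = XSD_INTEGER)
      for (fname in names(grp$combination)) {
        l_iri <- level_iris[[fname]][[grp$combination[[fname]]]]
        if (!is.null(l_iri)) {
          add_triple(sink, g_iri, vocab[["has level"]], l_iri)
        }
      }
      for (mk in grp$members) {
        add_triple(sink, g_iri, vocab[["has member"]], node_iris[[mk]])
      }
    }
  }
  sink
}

#' One-call conversion of an ISA-Tab archive to RDF
#'
#' Parses the archive, builds and merges the experiment graphs, and converts
#' everything to triples.
#'
#' @param path investigation file, directory or zip archive.
#' @param base_iri base IRI for minted identifiers.
#' @param framework packaged mapping framework (see [default_mappings()]).
#' @param mapping_paths extra user mapping files, order significant.
#' @param isa_ns ISA vocabulary namespace for fallback IRIs.
#' @return a [triple_sink()] (see [convert_to_rdf()]).
#' @examples
#' dir <- tempfile(); gt <- generate_fixture(fixture_spec(seed = 1), dir)
#' sink <- isatab_to_rdf(dir, "http://example.org/isa/demo/")
#' n_triples(sink)
#' @export
isatab_to_rdf <- function(path, base_iri,
                          framework = "obi", mapping_paths = character(),
                          isa_ns = ISA_NS) {
  inv <- parse_investigation(path)
  mappings <- default_mappings(framework, extra_paths = mapping_paths,
                               isa_ns = isa_ns)
  convert_to_rdf(inv, mappings, new_iri_policy(base_iri))
}
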