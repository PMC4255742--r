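#' Study-design interrogation queries
#'
#' Six read-only queries over the converted RDF recover the experimental
#' design: factors with their discrete levels, level counts per factor,
#' study-group combinations with sizes, minimum/maximum group size, a
#' balance check (balanced iff min == max), and a constructive annotation
#' step that adds a balanced-design type triple to the study-design
#' individual of each balanced study. Equivalent SPARQL 1.1 texts are
#' shipped under `system.file("queries", package = "isardf")` for use with
#' an external engine.
#' @name design-queries
NULL

# default predicate vocabulary when a sink carries none
default_vocab <- function() {
  toks <- .PREDICATE_TOKENS
  stats::setNames(as.list(paste0(ISA_NS, gsub(" ", "_", toks))), toks)
}

sink_vocab <- function(sink) sink$vocab %||% default_vocab()

study_iris <- function(sink) {
  v <- sink_vocab(sink)
  sort(unique(sink$o[match_triples(sink, p = v[["has study"]])]))
}

#' Factors and their discrete levels per study
#'
#' @param sink a [triple_sink()] produced by [convert_to_rdf()].
#' @return data.frame with columns `study`, `factor`, `level`, ordered
#'   lexicographically; zero rows when no factor has assigned levels.
#' @export
q_factors_levels <- function(sink) {
  v <- sink_vocab(sink)
  out <- data.frame(study = character(), factor = character(),
                    level = character(), stringsAsFactors = FALSE)
  for (st in study_iris(sink)) {
    st_lab <- label_of(sink, st)
    for (f in objects_of(sink, s = st, p = v[["has factor"]])) {
      f_lab <- label_of(sink, f)
      for (l in objects_of(sink, s = f, p = v[["has level"]])) {
        out <- rbind(out, data.frame(study = st_lab, factor = f_lab,
                                     level = label_of(sink, l),
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$study, out$factor, out$level), , drop = FALSE]
}

#' Number of distinct levels per factor
#'
#' Factors with zero assigned levels are omitted (they have no associated
#' discrete levels to count).
#' @inheritParams q_factors_levels
#' @return data.frame with columns `study`, `factor`, `n_levels`.
#' @export
q_count_levels <- function(sink) {
  fl <- q_factors_levels(sink)
  if (!nrow(fl)) {
    return(data.frame(study = character(), factor = character(),
                      n_levels = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(level ~ study + factor, data = fl,
                          FUN = function(x) length(unique(x)))
  names(agg)[3L] <- "n_levels"
  agg <- agg[order(agg$study, agg$factor), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Study groups and their sizes
#'
#' The combination is rendered as sorted `factor=level` pairs joined by
#' `";"`.
#' @inheritParams q_factors_levels
#' @return data.frame with columns `study`, `combination`, `size`.
#' @export
q_group_sizes <- function(sink) {
  v <- sink_vocab(sink)
  out <- data.frame(study = character(), combination = character(),
                    size = integer(), stringsAsFactors = FALSE)
  for (st in study_iris(sink)) {
    st_lab <- label_of(sink, st)
    for (g in objects_of(sink, s = st, p = v[["has group"]])) {
      size <- objects_of(sink, s = g, p = v[["has size"]])
      out <- rbind(out, data.frame(
        study = st_lab, combination = label_of(sink, g),
        size = as.integer(size[[1L]]), stringsAsFactors = FALSE))
    }
  }
  out[order(out$study, out$combination), , drop = FALSE]
}

#' Minimum and maximum group size per study
#'
#' Studies with no groups are omitted.
#' @inheritParams q_factors_levels
#' @return data.frame with columns `study`, `min_size`, `max_size`.
#' @export
q_min_max <- function(sink) {
  gs <- q_group_sizes(sink)
  if (!nrow(gs)) {
    return(data.frame(study = character(), min_size = integer(),
                      max_size = integer(), stringsAsFactors = FALSE))
  }
  mins <- stats::aggregate(size ~ study, data = gs, FUN = min)
  maxs <- stats::aggregate(size ~ study, data = gs, FUN = max)
  out <- data.frame(study = mins$study, min_size = mins$size,
                    max_size = maxs$size, stringsAsFactors = FALSE)
  out[order(out$study), , drop = FALSE]
}

#' Is the study design balanced?
#'
#' A design is balanced when the minimum group size equals the maximum.
#' @inheritParams q_factors_levels
#' @return data.frame with columns `study`, `balanced` (logical).
#' @export
check_balanced <- function(sink) {
  mm <- q_min_max(sink)
  data.frame(study = mm$study, balanced = mm$min_size == mm$max_size,
             stringsAsFactors = FALSE)
}

#' Annotate balanced study designs with a type triple
#'
#' For each balanced study, asserts that its study-design individual is of
#' the balanced-design class (one new triple; idempotent, so re-running adds
#' nothing). Imbalanced studies are untouched; a design previously annotated
#' balanced but computed imbalanced is reported as a discrepancy, never
#' silently un-annotated.
#'
#' @inheritParams q_factors_levels
#' @param balanced_class_iri class IRI to assert; defaults to the mapping
#'   set's "balanced design" entry captured at conversion time. With neither
#'   available this is a configuration error.
#' @return the sink, invisibly; `sink$last_annotation` holds the number of
#'   triples added and any discrepancy messages.
#' @export
annotate_balanced <- function(sink, balanced_class_iri = NULL) {
  cls <- balanced_class_iri %||% sink$balanced_class
  if (is.null(cls) || !nzchar(cls)) {
    stop("no balanced-design class IRI: pass balanced_class_iri or map ",
         "'balanced design' in the mapping set", call. = FALSE)
  }
  v <- sink_vocab(sink)
  bal <- check_balanced(sink)
  added <- 0L
  discrepancies <- character()
  for (st in study_iris(sink)) {
    st_lab <- label_of(sink, st)
    row <- bal[bal$study == st_lab, , drop = FALSE]
    if (!nrow(row)) next
    designs <- objects_of(sink, s = st, p = v[["has design"]])
    for (d in designs) {
      already <- length(match_triples(sink, s = d, p = RDF_TYPE, o = cls)) > 0L
      if (row$balanced[[1L]]) {
        if (add_triple(sink, d, RDF_TYPE, cls)) added <- added + 1L
      } else if (already) {
        discrepancies <- c(discrepancies, sprintf(
          "study '%s': design annotated as balanced but computed imbalanced",
          st_lab))
      }
    }
  }
  sink$last_annotation <- list(added = added, discrepancies = discrepancies)
  invisible(sink)
}

#' Full design report for a converted archive
#'
#' Runs the whole query suite and assembles, per study, the factors with
#' level lists, level counts, group combinations with sizes, min/max size
#' and the balance flag, plus any discrepancy messages from
#' [annotate_balanced()].
#'
#' @inheritParams q_factors_levels
#' @param annotate also run [annotate_balanced()] and record whether a
#'   triple was added.
#' @param balanced_class_iri forwarded to [annotate_balanced()].
#' @return an object of class `design_report`.
#' @export
design_report <- function(sink, annotate = FALSE, balanced_class_iri = NULL) {
  rep <- list(factors_levels = q_factors_levels(sink),
              level_counts = q_count_levels(sink),
              group_sizes = q_group_sizes(sink),
              min_max = q_min_max(sink),
              balanced = check_balanced(sink),
              warnings = unique(sink$warnings),
              annotation_added = NA_integer_,
              discrepancies = character())
  if (annotate) {
    annotate_balanced(sink, balanced_class_iri)
    rep$annotation_added <- sink$last_annotation$added
    rep$discrepancies <- sink$last_annotation$discrepancies
  }
  structure(rep, class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("Study design report\n")
  cat("===================\n")
  if (nrow(x$level_counts)) {
    cat("Factors (levels):\n")
    for (i in seq_len(nrow(x$level_counts))) {
      r <- x$level_counts[i, ]
      lv <- x$factors_levels
      lv <- lv$level[lv$study == r$study & lv$factor == r$factor]
      cat(sprintf("  %s / %s: %d level(s) {%s}\n", r$study, r$factor,
                  r$n_levels, paste(lv, collapse = ", ")))
    }
  } else cat("No factors with assigned levels.\n")
  if (nrow(x$group_sizes)) {
    cat("Study groups:\n")
    for (i in seq_len(nrow(x$group_sizes))) {
      r <- x$group_sizes[i, ]
      cat(sprintf("  %s / %s: size %d\n", r$study, r$combination, r$size))
    }
    for (i in seq_len(nrow(x$min_max))) {
      r <- x$min_max[i, ]
      b <- x$balanced$balanced[x$balanced$study == r$study]
      cat(sprintf("  %s: min %d, max %d -> %s\n", r$study, r$min_size,
                  r$max_size, if (b) "balanced" else "imbalanced"))
    }
  } else cat("No study groups.\n")
  if (!is.na(x$annotation_added)) {
    cat(sprintf("Balanced-design triples added: %d\n", x$annotation_added))
  }
  for (d in x$discrepancies) cat("DISCREPANCY:", d, "\n")
  if (length(x$warnings)) {
    cat(sprintf("%d validation warning(s)\n", length(x$warnings)))
  }
  invisible(x)
}
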