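# Build small ISA table files / studies in code for unit tests.

write_table <- function(lines, context = "STUDY") {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  parse_table_file(path, context)
}

tabline <- function(...) paste(c(...), collapse = "\t")

# a minimal study declaring the given factor and protocol names
toy_study <- function(id = "S1", factor_names = character(),
                      protocol_names = character()) {
  isa_study(
    identifier = id,
    factors = lapply(factor_names, factor_definition),
    protocols = lapply(protocol_names, protocol_definition)
  )
}

obi_mappings <- function(...) default_mappings("obi", extra_paths = c(...))

fresh_policy <- function(base = "http://example.org/isa/test/") {
  new_iri_policy(base)
}

# generate a fixture archive in a fresh temp dir, returning list(dir, gt)
gen_archive <- function(spec) {
  dir <- tempfile("fixture_")
  gt <- generate_fixture(spec, dir)
  list(dir = dir, gt = gt)
}

# full pipeline: archive dir -> converted sink
convert_archive <- function(dir, framework = "obi",
                            base = "http://example.org/isa/test/",
                            mapping_paths = character()) {
  isatab_to_rdf(dir, base, framework = framework,
                mapping_paths = mapping_paths)
}

# distill the query suite's view of one study's design, shaped like the
# brute-force oracle output so the two can be compared directly
sink_design <- function(sink, study_id) {
  fl <- q_factors_levels(sink)
  fl <- fl[fl$study == study_id, , drop = FALSE]
  lc <- q_count_levels(sink)
  lc <- lc[lc$study == study_id, , drop = FALSE]
  gs <- q_group_sizes(sink)
  gs <- gs[gs$study == study_id, , drop = FALSE]
  mm <- q_min_max(sink)
  mm <- mm[mm$study == study_id, , drop = FALSE]
  bal <- check_balanced(sink)
  bal <- bal[bal$study == study_id, , drop = FALSE]
  list(
    factors = lapply(split(fl$level, fl$factor), sort),
    level_counts = stats::setNames(lc$n_levels, lc$factor),
    groups = stats::setNames(as.list(gs$size), gs$combination),
    min_size = if (nrow(mm)) mm$min_size else NA_integer_,
    max_size = if (nrow(mm)) mm$max_size else NA_integer_,
    balanced = if (nrow(bal)) bal$balanced else NA
  )
}

bf_design <- function(bf, study_id) {
  st <- bf$studies[[study_id]]
  list(
    factors = lapply(st$factors, sort),
    level_counts = vapply(st$factors, length, 0L),
    groups = st$groups,
    min_size = as.integer(st$min_size),
    max_size = as.integer(st$max_size),
    balanced = st$balanced
  )
}

expect_same_design <- function(sd, bd) {
  expect_identical(sd$factors[order(names(sd$factors))],
                   bd$factors[order(names(bd$factors))])
  expect_identical(sd$level_counts[order(names(sd$level_counts))],
                   bd$level_counts[order(names(bd$level_counts))])
  expect_identical(sd$groups[order(names(sd$groups))],
                   bd$groups[order(names(bd$groups))])
  expect_identical(as.integer(sd$min_size), as.integer(bd$min_size))
  expect_identical(as.integer(sd$max_size), as.integer(bd$max_size))
  expect_identical(sd$balanced, bd$balanced)
}

# a randomly drawn fixture spec under a deterministic RNG stream
random_spec <- function(seed) {
  set.seed(seed)
  n_factors <- sample(1:3, 1L)
  factors <- stats::setNames(
    lapply(seq_len(n_factors), function(i) {
      paste0("f", i, "_l", seq_len(sample(2:4, 1L)))
    }),
    paste0("factor", seq_len(n_factors)))
  n_combos <- prod(vapply(factors, length, 0L))
  balanced <- sample(c(TRUE, FALSE), 1L)
  group_size <- if (balanced || n_combos == 1L) sample(1:6, 1L) else {
    gs <- sample(1:6, n_combos, replace = TRUE)
    while (length(unique(gs)) == 1L) gs <- sample(1:6, n_combos, replace = TRUE)
    gs
  }
  fixture_spec(factors = factors, group_size = group_size,
               factor_values_in = sample(c("study", "assay", "both"), 1L),
               seed = seed)
}
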