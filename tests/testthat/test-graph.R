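# Experiment-graph recovery: row segmentation, identity keys, process
# classification, study/assay merging and structural invariants.

test_that("a minimal source-protocol-sample row yields one process", {
  t <- write_table(c(tabline("Source Name", "Protocol REF", "Sample Name"),
                     tabline("src1", "growth", "sam1")))
  g <- build_graph(t, toy_study(protocol_names = "growth"), "STUDY")
  expect_length(g$materials, 2L)
  expect_length(g$processes, 1L)
  p <- g$processes[[1]]
  expect_identical(p$inputs, "material|SOURCE|src1")
  expect_identical(p$outputs, "material|SAMPLE|sam1")
  expect_identical(nrow(isardf:::graph_edges(g)), 2L)
})

test_that("process identity is name + parameters + inputs + outputs", {
  st <- toy_study(protocol_names = "growth")
  # same protocol name, different inputs -> two distinct applications
  t <- write_table(c(tabline("Source Name", "Protocol REF", "Sample Name"),
                     tabline("src1", "growth", "sam1"),
                     tabline("src2", "growth", "sam1")))
  g <- build_graph(t, st, "STUDY")
  expect_length(g$materials, 3L)
  expect_length(g$processes, 2L)

  # identical tuples across rows merge into one application
  t2 <- write_table(c(tabline("Source Name", "Protocol REF", "Sample Name"),
                      tabline("src1", "growth", "sam1"),
                      tabline("src1", "growth", "sam1")))
  g2 <- build_graph(t2, st, "STUDY")
  expect_length(g2$processes, 1L)

  # same name and wiring but a different Parameter Value -> two keys
  t3 <- write_table(c(
    tabline("Source Name", "Protocol REF", "Parameter Value[temp]",
            "Sample Name"),
    tabline("src1", "growth", "30", "sam1"),
    tabline("src1", "growth", "37", "sam1")))
  g3 <- build_graph(t3, st, "STUDY")
  expect_length(g3$processes, 2L)

  # materials are identified by their strings: Source "A" twice -> one key
  expect_identical(element_key(g$materials[["material|SOURCE|src1"]]),
                   "material|SOURCE|src1")
})

test_that("processes classify by the kinds of their inputs and outputs", {
  st <- toy_study(protocol_names = c("extraction", "labeling",
                                     "hybridization", "normalization"))
  t <- write_table(c(
    tabline("Sample Name", "Protocol REF", "Extract Name", "Protocol REF",
            "Labeled Extract Name", "Protocol REF", "Raw Data File",
            "Protocol REF", "Derived Data File"),
    tabline("sam1", "extraction", "ext1", "labeling", "lex1",
            "hybridization", "raw1.dat", "normalization", "norm1.dat")),
    context = "ASSAY")
  g <- build_graph(t, st, "ASSAY")
  cats <- vapply(g$processes, classify_process, "")
  names(cats) <- vapply(g$processes, `[[`, "", "protocol_name")
  expect_identical(unname(cats[c("extraction", "labeling")]),
                   rep("MATERIAL_TO_MATERIAL", 2L))
  expect_identical(unname(cats[["hybridization"]]), "MATERIAL_TO_DATA")
  expect_identical(unname(cats[["normalization"]]), "DATA_TO_DATA")
})

test_that("consecutive Protocol REF columns chain via anonymous materials", {
  t <- write_table(c(
    tabline("Source Name", "Protocol REF", "Protocol REF", "Sample Name"),
    tabline("src1", "wash", "stain", "sam1")))
  g <- build_graph(t, toy_study(protocol_names = c("wash", "stain")), "STUDY")
  expect_length(g$processes, 2L)
  anon <- names(g$materials)[startsWith(names(g$materials),
                                        "material|OTHER_MATERIAL|")]
  expect_length(anon, 1L)
  # the chain is connected: wash outputs the anon node, stain consumes it
  outs <- unlist(lapply(g$processes, `[[`, "outputs"))
  ins <- unlist(lapply(g$processes, `[[`, "inputs"))
  expect_true(anon %in% outs && anon %in% ins)
})

test_that("empty node cells are skipped and rows stay connected", {
  t <- write_table(c(
    tabline("Source Name", "Protocol REF", "Sample Name", "Protocol REF",
            "Extract Name"),
    tabline("src1", "collect", "", "extract", "ext1")))
  g <- build_graph(t, toy_study(protocol_names = c("collect", "extract")),
                   "STUDY")
  # both protocols apply between src1 and ext1 (chained through an
  # anonymous stand-in for the missing sample)
  expect_length(g$processes, 2L)
  expect_false("material|SAMPLE|" %in% names(g$materials))
})

test_that("characteristics attach to the nearest node column to their left", {
  t <- write_table(c(
    tabline("Source Name", "Characteristics[OBI:organism]", "Term Source REF",
            "Term Accession Number", "Protocol REF", "Sample Name",
            "Characteristics[status]"),
    tabline("src1", "Homo sapiens", "NCBItaxon", "9606", "collect", "sam1",
            "healthy")))
  src <- list(ontology_source("NCBItaxon",
                              "http://purl.obolibrary.org/obo/NCBITaxon_"))
  g <- build_graph(t, toy_study(protocol_names = "collect"), "STUDY",
                   sources = src)
  source_node <- g$materials[["material|SOURCE|src1"]]
  expect_length(source_node$characteristics, 1L)
  expect_identical(source_node$characteristics[[1]]$value$resolved_iri,
                   "http://purl.obolibrary.org/obo/NCBITaxon_9606")
  expect_identical(source_node$declared_type_iri,
                   "http://purl.obolibrary.org/obo/NCBITaxon_9606")
  sample_node <- g$materials[["material|SAMPLE|sam1"]]
  expect_identical(sample_node$characteristics[[1]]$category, "status")
})

test_that("undeclared protocols and factors produce warnings, not errors", {
  t <- write_table(c(
    tabline("Source Name", "Protocol REF", "Sample Name",
            "Factor Value[dose]"),
    tabline("src1", "mystery", "sam1", "low")))
  g <- build_graph(t, toy_study(factor_names = "exposure",
                                protocol_names = "growth"), "STUDY")
  expect_true(any(grepl("mystery", g$warnings)))
  expect_true(any(grepl("dose", g$warnings)))
  # the assignment is kept despite the warning
  expect_length(g$factor_assignments, 1L)
})

test_that("a cyclic table is rejected as a structural error", {
  t <- write_table(c(
    tabline("Sample Name", "Protocol REF", "Sample Name"),
    tabline("a", "p", "b"),
    tabline("b", "p", "a")))
  expect_error(build_graph(t, toy_study(protocol_names = "p"), "STUDY"),
               "cycle")
})

test_that("study and assay graphs merge on shared sample names", {
  st <- toy_study(protocol_names = c("collect", "extract"))
  study_t <- write_table(c(
    tabline("Source Name", "Protocol REF", "Sample Name"),
    tabline("src1", "collect", "sam1"), tabline("src2", "collect", "sam2"),
    tabline("src3", "collect", "sam3"), tabline("src4", "collect", "sam4")))
  assay_t <- write_table(c(
    tabline("Sample Name", "Protocol REF", "Raw Data File"),
    tabline("sam1", "extract", "r1.dat"),
    tabline("sam2", "extract", "r2.dat")), context = "ASSAY")
  sg <- build_graph(study_t, st, "STUDY")
  ag <- build_graph(assay_t, st, "ASSAY")
  m <- merge_study_assay(sg, list(ag))
  samples <- names(m$materials)[startsWith(names(m$materials),
                                           "material|SAMPLE|")]
  expect_length(samples, 4L)

  # assay referencing an unknown sample keeps it, with a warning
  dangle_t <- write_table(c(
    tabline("Sample Name", "Protocol REF", "Raw Data File"),
    tabline("sam9", "extract", "r9.dat")), context = "ASSAY")
  dg <- build_graph(dangle_t, st, "ASSAY")
  m2 <- merge_study_assay(sg, list(ag, dg))
  samples2 <- names(m2$materials)[startsWith(names(m2$materials),
                                             "material|SAMPLE|")]
  expect_length(samples2, 5L)
  expect_true(any(grepl("dangling", m2$warnings)))
})

test_that("merging is order-independent on element-key sets", {
  x <- gen_archive(fixture_spec(
    factors = list(dose = c("low", "high")), group_size = 2L, seed = 5))
  inv <- parse_investigation(x$dir)
  st <- inv$studies[[1]]
  sg <- build_graph(st$study_table, st, "STUDY", inv$ontology_sources)
  ags <- lapply(st$assays, function(a)
    build_graph(a$table, st, "ASSAY", inv$ontology_sources))
  m1 <- merge_study_assay(sg, ags)
  m2 <- merge_study_assay(sg, rev(ags))
  keyset <- function(m) sort(c(names(m$materials), names(m$data),
                               names(m$processes)))
  expect_identical(keyset(m1), keyset(m2))
})

test_that("node conservation: distinct (kind, name) pairs over all tables", {
  x <- gen_archive(fixture_spec(
    factors = list(dose = c("low", "high"), time = c("1h", "4h")),
    group_size = 3L, seed = 9))
  inv <- parse_investigation(x$dir)
  g <- build_study_graph(inv$studies[[1]], inv$ontology_sources)
  bf <- brute_force_design(x$dir)$studies$S1$node_counts
  count_kind <- function(prefix) {
    sum(startsWith(names(g$materials), prefix))
  }
  expect_identical(count_kind("material|SOURCE|"), bf$SOURCE)
  expect_identical(count_kind("material|SAMPLE|"), bf$SAMPLE)
  expect_identical(count_kind("material|EXTRACT|"), bf$EXTRACT)
  expect_identical(count_kind("material|LABELED_EXTRACT|"),
                   bf$LABELED_EXTRACT)
  expect_identical(length(g$data), bf$DATA)
})

test_that("edges are strictly bipartite between nodes and processes", {
  x <- gen_archive(fixture_spec(seed = 13))
  inv <- parse_investigation(x$dir)
  g <- build_study_graph(inv$studies[[1]], inv$ontology_sources)
  em <- isardf:::graph_edges(g)
  from_proc <- startsWith(em[, 1], "process|")
  to_proc <- startsWith(em[, 2], "process|")
  expect_true(all(xor(from_proc, to_proc)))
})

test_that("repeated characteristics with different values warn and keep both", {
  t <- write_table(c(
    tabline("Source Name", "Characteristics[sex]", "Protocol REF",
            "Sample Name"),
    tabline("src1", "male", "collect", "sam1"),
    tabline("src1", "female", "collect", "sam2")))
  g <- build_graph(t, toy_study(protocol_names = "collect"), "STUDY")
  expect_true(any(grepl("multiple values", g$warnings)))
  expect_length(g$materials[["material|SOURCE|src1"]]$characteristics, 2L)
})
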