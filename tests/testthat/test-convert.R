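# RDF conversion: annotation exploitation, identity of individuals,
# attribute emission, study-group inference and determinism.

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

test_that("an annotated organism characteristic types the source material", {
  x <- gen_archive(fixture_spec(seed = 2, group_size = 1L))
  sink <- convert_archive(x$dir)
  df <- triples(sink)
  taxon <- "http://purl.obolibrary.org/obo/NCBITaxon_9606"
  typed <- df$subject[df$predicate == RDF_TYPE & df$object == taxon]
  sources <- unique(df$subject[grepl("/source/", df$subject)])
  expect_true(all(sources %in% typed))
  # the characteristic category resolves to the OBI organism class
  expect_true("http://purl.obolibrary.org/obo/OBI_0100026" %in% df$object)
})

test_that("a sample appearing in study and assay tables is one individual", {
  x <- gen_archive(fixture_spec(seed = 4))
  sink <- convert_archive(x$dir)
  df <- triples(sink)
  sample_iris <- unique(df$subject[grepl("/sample/", df$subject)])
  bf <- brute_force_design(x$dir)
  expect_identical(length(sample_iris), bf$studies$S1$node_counts$SAMPLE)
  # and no IRI is minted for two distinct element keys: labels are unique
  labs <- df$object[df$subject %in% sample_iris &
                    df$predicate == "http://www.w3.org/2000/01/rdf-schema#label"]
  expect_identical(length(unique(labs)), length(sample_iris))
})

test_that("factor levels attach to factors and groups, never to samples", {
  x <- gen_archive(fixture_spec(seed = 6))
  sink <- convert_archive(x$dir)
  df <- triples(sink)
  level_iris <- unique(df$subject[grepl("/factor_value/", df$subject)])
  sample_iris <- unique(df$subject[grepl("/sample/", df$subject)])
  expect_gt(length(level_iris), 0L)
  bad <- df[df$subject %in% sample_iris & df$object %in% level_iris, ]
  expect_identical(nrow(bad), 0L)
  factor_iris <- unique(df$subject[grepl("/study_factor/", df$subject)])
  from_factors <- df[df$subject %in% factor_iris &
                     df$object %in% level_iris, ]
  expect_gt(nrow(from_factors), 0L)
})

test_that("study groups partition the fully-assigned samples", {
  spec <- fixture_spec(
    factors = list(dose = c("low", "mid", "high"), sex = c("m", "f")),
    group_size = 5L, seed = 8)
  x <- gen_archive(spec)
  sink <- convert_archive(x$dir)
  groups <- sink$study_groups$S1
  expect_length(groups, 6L)
  expect_true(all(vapply(groups, `[[`, 0L, "size") == 5L))
  members <- unlist(lapply(groups, `[[`, "members"))
  expect_identical(anyDuplicated(members), 0L)
  expect_identical(length(members), 30L)
})

test_that("group inference handles edge cases per the validation contract", {
  # direct grouping: dose low/low/high/high -> 2 groups of 2
  st <- toy_study(factor_names = "dose", protocol_names = "collect")
  t <- write_table(c(
    tabline("Source Name", "Protocol REF", "Sample Name",
            "Factor Value[dose]"),
    tabline("src1", "collect", "sam1", "low"),
    tabline("src2", "collect", "sam2", "low"),
    tabline("src3", "collect", "sam3", "high"),
    tabline("src4", "collect", "sam4", "high")))
  g <- build_graph(t, st, "STUDY")
  groups <- infer_study_groups(g, st)
  expect_length(groups, 2L)
  expect_identical(vapply(groups, `[[`, 0L, "size"), c(2L, 2L))

  # no declared factors -> empty group list
  g2 <- build_graph(t, toy_study(protocol_names = "collect"), "STUDY")
  expect_length(infer_study_groups(g2, toy_study()), 0L)

  # a sample with a partial factor vector is excluded and reported
  st2 <- toy_study(factor_names = c("dose", "time"),
                   protocol_names = "collect")
  t2 <- write_table(c(
    tabline("Source Name", "Protocol REF", "Sample Name",
            "Factor Value[dose]", "Factor Value[time]"),
    tabline("src1", "collect", "sam1", "low", "1h"),
    tabline("src2", "collect", "sam2", "low", "")))
  g3 <- build_graph(t2, st2, "STUDY")
  grp <- infer_study_groups(g3, st2)
  expect_length(grp, 1L)
  expect_identical(attr(grp, "partial"), "material|SAMPLE|sam2")

  # conflicting levels for one (sample, factor) -> hard validation error
  t3 <- write_table(c(
    tabline("Source Name", "Protocol REF", "Sample Name",
            "Factor Value[dose]"),
    tabline("src1", "collect", "sam1", "low"),
    tabline("src1", "collect", "sam1", "high")))
  g4 <- build_graph(t3, st, "STUDY")
  expect_error(infer_study_groups(g4, st),
               class = "isardf_validation_error")
})

test_that("attribute emission: annotated, literal and extension cases", {
  ext <- system.file("extdata", "mappings", "tissue_extension.csv",
                     package = "isardf")
  t <- write_table(c(
    tabline("Source Name", "Characteristics[OBI:organism]", "Term Source REF",
            "Term Accession Number", "Characteristics[OBI:tissue specimen]",
            "Protocol REF", "Sample Name"),
    tabline("src1", "Homo sapiens", "NCBItaxon", "9606", "liver",
            "collect", "sam1")))
  st <- toy_study(protocol_names = "collect")
  src <- list(ontology_source("NCBItaxon",
                              "http://purl.obolibrary.org/obo/NCBITaxon_"))
  inv <- isa_investigation("I1", ontology_sources = src,
                           studies = list(st))
  g <- build_graph(t, st, "STUDY", sources = src)
  sink <- convert_to_rdf(inv, default_mappings("obi", extra_paths = ext),
                         fresh_policy(), graphs = list(g))
  df <- triples(sink)
  # tissue value individual linked part-of to the organism value individual
  tissue_type <- "http://purl.obolibrary.org/obo/OBI_0001479"
  tissue_iri <- df$subject[df$predicate == RDF_TYPE & df$object == tissue_type]
  expect_length(tissue_iri, 1L)
  partof <- df[df$subject == tissue_iri &
               df$predicate == "http://purl.obolibrary.org/obo/BFO_0000050", ]
  expect_identical(nrow(partof), 1L)
  organism_iri <- df$subject[df$predicate == RDF_TYPE &
    df$object == "http://purl.obolibrary.org/obo/OBI_0100026"]
  expect_identical(partof$object, organism_iri)
  # the literal-only tissue value carries a plain literal, no term type
  hv <- df[df$subject == tissue_iri &
           df$predicate == paste0(ISA_NS, "has_value"), ]
  expect_identical(hv$object, "liver")
  expect_true(all(hv$literal))
})

test_that("conversion is deterministic and invariant to row permutation", {
  x <- gen_archive(fixture_spec(
    factors = list(dose = c("low", "high")), group_size = 3L, seed = 10))
  inv <- parse_investigation(x$dir)
  maps <- obi_mappings()
  nt1 <- write_ntriples(convert_to_rdf(inv, maps, fresh_policy()))
  nt2 <- write_ntriples(convert_to_rdf(inv, maps, fresh_policy()))
  expect_identical(nt1, nt2)

  # permute study-table rows: identities unchanged -> isomorphic output
  inv2 <- inv
  set.seed(99)
  inv2$studies[[1]]$study_table$rows <-
    sample(inv$studies[[1]]$study_table$rows)
  s1 <- convert_to_rdf(inv, maps, fresh_policy())
  s2 <- convert_to_rdf(inv2, maps, fresh_policy())
  expect_identical(n_triples(s2), n_triples(s1))
  expect_identical(q_factors_levels(s2), q_factors_levels(s1))
  expect_identical(q_group_sizes(s2), q_group_sizes(s1))
  # type-triple multisets agree up to IRI renaming
  typemult <- function(s) sort(table(triples(s)$object[
    triples(s)$predicate == RDF_TYPE]))
  expect_identical(typemult(s2), typemult(s1))
})

test_that("swapping the mapping framework changes types, not individuals", {
  x <- gen_archive(fixture_spec(seed = 12))
  s_obi <- convert_archive(x$dir, framework = "obi")
  s_prov <- convert_archive(x$dir, framework = "provo")
  subj <- function(s) unique(triples(s)$subject)
  expect_identical(length(subj(s_obi)), length(subj(s_prov)))
  types <- function(s) unique(triples(s)$object[
    triples(s)$predicate == RDF_TYPE])
  expect_true("http://www.w3.org/ns/prov#Activity" %in% types(s_prov))
  expect_false("http://www.w3.org/ns/prov#Activity" %in% types(s_obi))
  expect_true("http://purl.obolibrary.org/obo/OBI_0000094" %in% types(s_obi))
})
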