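# ISA-Tab reading: header recognition, annotation resolution, table and
# investigation parsing, and the write/parse round trip.

test_that("header recognition covers the ISA vocabulary and is total", {
  cases <- list(
    list("Characteristics[OBI:organism]", "CHARACTERISTICS", "OBI:organism"),
    list("Source Name", "SOURCE_NAME", ""),
    list("Sample Name", "SAMPLE_NAME", ""),
    list("Labeled Extract Name", "LABELED_EXTRACT_NAME", ""),
    list("Factor Value[dose]", "FACTOR_VALUE", "dose"),
    list("Parameter Value[temperature]", "PARAMETER_VALUE", "temperature"),
    list("Protocol REF", "PROTOCOL_REF", ""),
    list("Term Source REF", "TERM_SOURCE_REF", ""),
    list("Term Accession Number", "TERM_ACCESSION_NUMBER", ""),
    list("Raw Data File", "RAW_DATA_FILE", ""),
    list("Derived Data File", "DERIVED_DATA_FILE", ""),
    list("Array Data File", "OTHER_DATA_FILE", ""),
    list("Unit", "UNIT", ""),
    list("Comment[batch]", "COMMENT", "batch"),
    list("Weird Column", "OTHER", ""),
    # malformed bracket qualifiers degrade to OTHER, never an error
    list("Characteristics[", "OTHER", ""),
    list("Characteristics]x[", "OTHER", "")
  )
  for (cs in cases) {
    h <- recognize_header(cs[[1]], 0L)
    expect_identical(h$kind, cs[[2]], label = cs[[1]])
    expect_identical(h$qualifier, cs[[3]], label = cs[[1]])
  }
})

test_that("header matching is case-insensitive but qualifiers are verbatim", {
  h <- recognize_header("cHaRacteristics[OBI:Tissue Specimen]", 3L)
  expect_identical(h$kind, "CHARACTERISTICS")
  expect_identical(h$qualifier, "OBI:Tissue Specimen")
  expect_identical(recognize_header("PROTOCOL ref", 0L)$kind, "PROTOCOL_REF")
})

test_that("recognition is idempotent on the rendered canonical form", {
  for (txt in c("source name", "Characteristics[OBI:organism]",
                "factor value[dose]", "Protocol REF", "Unit[mass]")) {
    h1 <- recognize_header(txt, 0L)
    h2 <- recognize_header(isardf:::render_header(h1), 0L)
    expect_identical(h2$kind, h1$kind)
    expect_identical(h2$qualifier, h1$qualifier)
  }
})

test_that("annotations resolve against declared ontology sources", {
  sources <- list(
    ontology_source("NCBItaxon", "http://purl.obolibrary.org/obo/NCBITaxon_"))
  a <- resolve_annotation("Homo sapiens", "NCBItaxon", "9606", sources)
  expect_identical(a$resolved_iri,
                   "http://purl.obolibrary.org/obo/NCBITaxon_9606")
  expect_identical(a$text, "Homo sapiens")

  # empty value -> empty annotation
  e <- resolve_annotation("", "", "", sources)
  expect_true(isardf:::is_empty_annotation(e))

  # literal fallback: unknown source keeps the text, no IRI
  l <- resolve_annotation("liver", "", "", sources)
  expect_identical(l$text, "liver")
  expect_identical(l$resolved_iri, "")

  # an accession that is already an absolute IRI is used as-is
  iri <- "http://purl.obolibrary.org/obo/NCBITaxon_9606"
  d <- resolve_annotation("Homo sapiens", "", iri, list())
  expect_identical(d$resolved_iri, iri)
})

test_that("table files parse with padding, trimming and blank-line rules", {
  t <- write_table(c(
    tabline("Source Name", "Protocol REF", "Sample Name"),
    tabline(" src1 ", "growth", "sam1"),
    tabline("src2", "growth"),          # short row -> padded
    "", ""                              # trailing blanks dropped
  ))
  expect_length(t$headers, 3L)
  expect_length(t$rows, 2L)
  expect_identical(t$rows[[1]], c("src1", "growth", "sam1"))
  expect_identical(t$rows[[2]], c("src2", "growth", ""))

  # header-only and CRLF files are fine; quoted cells are unwrapped
  h <- write_table(tabline("Source Name", "Sample Name"))
  expect_length(h$rows, 0L)
  p <- tempfile(); writeBin(charToRaw(
    "Source Name\tSample Name\r\n\"src 1\"\tsam1\r\n"), p)
  q <- parse_table_file(p, "STUDY")
  expect_identical(q$rows[[1]], c("src 1", "sam1"))
})

test_that("assay tables expose the extract / labeled extract chain", {
  x <- gen_archive(fixture_spec(seed = 3))
  inv <- parse_investigation(x$dir)
  kinds <- vapply(inv$studies[[1]]$assays[[1]]$table$headers, `[[`, "", "kind")
  expect_true(all(c("EXTRACT_NAME", "LABELED_EXTRACT_NAME", "RAW_DATA_FILE")
                  %in% kinds))
})

test_that("investigation parsing recovers declarations and fails loudly", {
  x <- gen_archive(fixture_spec(seed = 7))
  inv <- parse_investigation(x$dir)
  expect_s3_class(inv, "isa_investigation")
  expect_length(inv$studies, 1L)
  st <- inv$studies[[1]]
  expect_identical(vapply(st$factors, `[[`, "", "name"), "dose")
  expect_true("sample collection" %in% vapply(st$protocols, `[[`, "", "name"))
  expect_identical(vapply(inv$ontology_sources, `[[`, "", "name"),
                   c("NCBItaxon", "OBI"))

  # referenced table file missing -> format error naming the file
  bad <- tempfile(); dir.create(bad)
  writeLines(c("INVESTIGATION", "STUDY",
               "Study Identifier\tS1",
               "Study File Name\ts_missing.txt"),
             file.path(bad, "i_investigation.txt"))
  expect_error(parse_investigation(bad), "s_missing.txt")

  # no STUDY block -> format error naming the section
  nost <- tempfile(); dir.create(nost)
  writeLines(c("INVESTIGATION", "Investigation Identifier\tX"),
             file.path(nost, "i_investigation.txt"))
  expect_error(parse_investigation(nost), "STUDY")

  expect_error(parse_investigation(tempfile()), "no such file")
})

test_that("duplicate ontology sources warn and last declaration wins", {
  d <- tempfile(); dir.create(d)
  writeLines(tabline("Source Name", "Sample Name"), file.path(d, "s_S1.txt"))
  writeLines(c("ONTOLOGY SOURCE REFERENCE",
               tabline("Term Source Name", "OBI", "OBI"),
               tabline("Term Source File", "http://a/", "http://b/"),
               "INVESTIGATION", "STUDY",
               "Study Identifier\tS1", "Study File Name\ts_S1.txt"),
             file.path(d, "i_investigation.txt"))
  expect_warning(inv <- parse_investigation(d), "declared twice")
  expect_identical(inv$ontology_sources[[1]]$file_or_base, "http://b/")
})

test_that("zip archives are accepted", {
  x <- gen_archive(fixture_spec(seed = 11))
  zipfile <- tempfile(fileext = ".zip")
  files <- list.files(x$dir, full.names = TRUE)
  status <- system2("python", c("-m", "zipfile", "-c", zipfile, files),
                    stdout = FALSE)
  expect_identical(status, 0L)
  inv <- parse_investigation(zipfile)
  expect_identical(inv$studies[[1]]$identifier, "S1")
})

test_that("parse -> write -> parse is the identity on the model", {
  for (seed in c(7L, 23L)) {
    x <- gen_archive(fixture_spec(
      factors = list(dose = c("low", "high"), time = c("1h", "4h", "24h")),
      group_size = 2L, seed = seed))
    m1 <- parse_investigation(x$dir)
    out <- tempfile()
    write_isatab(m1, out)
    m2 <- parse_investigation(out)
    expect_identical(model_fingerprint(m2), model_fingerprint(m1))
  }
})
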