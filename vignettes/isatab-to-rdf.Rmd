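---
title: "From ISA-Tab tables to a semantic experiment graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ISA-Tab tables to a semantic experiment graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isardf)
```

## The model

An ISA-Tab archive describes an experiment as tables, but the thing the
tables *denote* is a directed acyclic graph: material entities (sources,
samples, extracts, labeled extracts) and data files are nodes, and each row
of a study or assay table traces one path through that graph, with
`Protocol REF` columns marking the processes that transform the node on
their left into the node on their right. `isardf` recovers that graph,
types its elements through ontology mapping files, and serialises the
result as RDF so that the design becomes queryable.

Three modelling rules do most of the work:

* **Identity.** Materials and data files are identified by their kind and
  name: the string `sam01` in a study table and in an assay table is the
  same sample, which is what lets the study and assay graphs merge. A
  protocol application is identified by the tuple (protocol name,
  canonicalised parameter values, sorted inputs, sorted outputs): two rows
  naming the same protocol denote one application if and only if the whole
  tuple matches. This reproduces pooling (many inputs converging on one
  output across rows remain distinct applications unless the full tuple
  agrees) and splitting.
* **Attribute attachment.** `Characteristics[...]` columns qualify the
  nearest node column to their left, `Parameter Value[...]` the nearest
  `Protocol REF` to their left, and `Term Source REF` / `Term Accession
  Number` / `Unit` columns qualify the nearest annotatable column to their
  left (a unit may carry its own term-source pair). This is the standard
  ISA-Tab column-pairing convention.
* **Process classification.** After assembly, every process is classified
  by the kinds of its inputs and outputs: material→material (e.g. sample
  to extract), material→data (e.g. labeled extract to raw data file) or
  data→data (e.g. raw to derived file). A fourth `MIXED` category exists
  for inputs or outputs of mixed kind; it is reported in validation output
  rather than silently bucketed into one of the three.

## Mapping files and the semantic framework

The conversion engine is deliberately decoupled from any one ontology.
Delimited mapping files carry two kinds of rows: *type rows* (`element,
label, class IRI[, context]`) and *property rows* (subject element, subject
label and class IRI, property label and IRI, object label, and an object
that is either a class IRI or a reference to another ISA element). The
optional fourth field of a type row is our extension: the tabular grammar
has no other way to express that a `Protocol REF` means *material
processing* (OBI_0000094) in a study file but *planned process*
(OBI_0000011) in an assay file, and that distinction is load-bearing.

Resolution precedence is: later files beat earlier files; within a file, an
(element, context) entry beats an (element, ANY) entry; a bracket-qualified
entry (`Characteristics[OBI:organism]`) beats the bare family name. With no
match at all the element falls back to a minted IRI in a configurable ISA
vocabulary namespace (default `http://purl.org/isaterms/`), so resolution
is total and a conversion never fails for want of a mapping. The packaged
`isa.csv` enumerates the ISA-Tab 1.0 vocabulary one-to-one into that
namespace (our enumeration — flagged as such in the file) and also carries
the predicate vocabulary (`has_member`, `has_size`, `has_input`, ...) as
ordinary overridable rows. The `obi.csv`, `provo.csv` and `sio.csv`
frameworks override types only where we are confident of the target class;
`sio.csv` is intentionally skeletal. The balanced-design class defaults to
a stand-in row in `isa.csv` ("balanced design") precisely so users can
swap in the STATO term without touching code.

User annotations outrank generic typing where they are specific: an
annotated `Characteristics[OBI:organism]` value types its bearer directly
(the source becomes an instance of, say, `NCBITaxon_9606`), and property
rows add relations between sibling characteristic values of one bearer
(the shipped `tissue_extension.csv` relates a tissue specimen to its
organism via BFO part-of).

## Identifiers

Individuals get IRIs of the form `<base IRI>/<type>/<counter>`, one counter
per type, starting at 1, incremented in order of creation, with an element
identity key minted at most once. Cross-run stability comes from a fixed
traversal order: investigation, then per study its design, factors, levels
(lexicographic within a factor — first-appearance order would leak row
order into the IRIs), protocols, assays, then materials and data in table
insertion order (row-major), then processes, then groups. Two conversions
of one archive therefore produce byte-identical canonical (sorted)
N-Triples, while permuting input rows yields an isomorphic graph whose
query answers are unchanged.

## Study groups and the balance procedure

A sample's factor-value vector is the union of its `Factor Value`
assignments across study and assay files (the format allows either
placement). Groups are the distinct complete vectors — samples assigned
every declared factor — and carry their member sets and sizes as literals.
Three deliberate choices, where the underlying format is silent:

* Samples with *partial* vectors are excluded from grouping and listed in
  the validation report; a group defined on a strict subset of factors
  would not be comparable with the others.
* *Conflicting* levels for one (sample, factor) pair are a hard validation
  error rather than a warning: group membership would be ambiguous, and
  silently picking a level would fabricate a design.
* In assay context an assignment binds to the row's leftmost sample node
  (falling back to the leftmost material), a deterministic anchor for
  designs where factors only make sense at the assay level.

No triple ever links a sample directly to a factor value: levels attach to
factors, and groups attach to levels and members. The balance procedure is
then three reads and a write: min and max of the group sizes per study,
`balanced ⇔ min == max`, and for each balanced study one type triple on
its *study-design individual* asserting the balanced-design class. We
annotate the design individual (not the study, not a plan) because the
balance is a property of the design; the choice is recorded in the report.
The step is idempotent — the sink deduplicates statements — and a design
already annotated balanced that computes imbalanced is reported as a
discrepancy, never un-annotated, since detecting mis-annotation is the
point of the exercise.

## The synthetic-data generator

`generate_fixture()` emulates the canonical transcription-profiling
archive: sources collected into samples in the study table (with factor
values realising the requested group design), and an assay table carrying
each sample through extraction → labeling → hybridization into a raw data
file. Defaults are one study, one two-level factor (`dose`: low/high),
three replicates per combination — a small but realistic intervention
design — with organism annotations (Homo sapiens, NCBItaxon 9606) switched
on. Group sizes accept a per-combination vector to build imbalanced
designs; the seed fully determines the output bytes (row order is the only
randomised feature, so grouping never depends on generation order).

What it does *not* emulate: hand-edited irregularities (sparse cells,
inconsistent naming), pooling/splitting topologies, multi-valued
characteristics, measurement file contents (data files are names only),
and ISA configuration/template validation. Passing tests therefore
demonstrate correctness of the parsing/graph/conversion/query contracts on
well-formed archives, not robustness against every curation pathology —
though the parser's padding, trimming and warning rules are tested on
constructed degenerate tables separately.

The test suite checks the pipeline against two independent references: a
brute-force oracle (`brute_force_design()`) that recomputes factors,
levels, groups, sizes and balance straight from the table cells without
graph or RDF machinery, over dozens of seeded random designs (1–3 factors,
2–4 levels, group sizes 1–6, balanced and imbalanced, factor values in
study, assay or both files); and, for the serialisers, an independent RDF
stack (Python rdflib) that re-parses our N-Triples, Turtle and RDF/XML
output and confirms statement counts and graph isomorphism. Problem sizes
(up to ~60 fixtures of ≤ 384 samples) keep the whole suite under a minute
while covering every combination class.

## Numerical and degenerate-input choices

* Header matching is case-insensitive on the fixed vocabulary; qualifiers
  are verbatim (their `PREFIX:label` text matters downstream). Malformed
  bracket qualifiers (`Characteristics[`) degrade to `OTHER`, never error.
* Short rows are padded with empty cells; empty node cells are skipped,
  with protocol runs chaining across the gap through minted anonymous
  intermediates (one per row and protocol column), so every process keeps
  explicit inputs and outputs.
* Consecutive `Protocol REF` columns chain the same way.
* Duplicate ontology-source declarations: last wins, with a warning.
  Repeated characteristics with different values on one material: kept as
  multi-valued, with a warning — the format does not forbid them.
* Cycles (an output name reused upstream) are a structural error: the DAG
  assumption is load-bearing for everything downstream.
* Sizes are typed `xsd:integer`; other literals are plain strings.

## Limitations

* The query suite is implemented as triple-pattern matching over the
  package's own sink; the shipped `.rq` files are equivalents for an
  external SPARQL engine, not the execution path.
* No OWL reasoning or classification is performed over the target
  ontologies, and no network lookups: annotation resolution uses the
  declared term-source bases only.
* Legacy assay-column variants (`Data Transformation Name`,
  `Normalization Name`) map to `OTHER` and are visible in validation
  output rather than modelled.
* The ISA vocabulary namespace and the default balanced-design class are
  configurable stand-ins, not community-ratified IRIs; override them via
  mapping files for interoperability with a specific resource.
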