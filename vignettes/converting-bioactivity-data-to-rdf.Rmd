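---
title: "Converting ChEMBL-schema bioactivity data to linked open data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting ChEMBL-schema bioactivity data to linked open data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemblrdf)
```

## The conversion in one picture

A ChEMBL-style relational snapshot has seven in-memory tables (molecules,
properties, assays, assay-to-target assignments, targets, activities,
documents).  The converter maps each row onto a fixed triple pattern and
unions the results into one graph:

* activities are the hub: each links to its assay, its molecule, and
  cites its source document;
* assays reach targets through intermediate *target-description*
  constructs, because the curation confidence score qualifies the
  assay-to-target mapping, not the assay;
* molecules and protein targets are modelled as ontology classes,
  everything else as instances.

Two rows are deliberately dropped: assays whose type is undefined, and
the sentinel "unpublished" document (`doc_id = -1`), which is not a valid
article.  Everything else is conserved one-to-one, which is what makes
count-based validation meaningful.

## Ontological commitments and their assumptions

The conversion is pragmatic, not a full ontological model of
pharmacology.  Where the source column's meaning is clear, a community
term is used (CiTO for literature provenance, BIBO for article metadata,
CHEMINF/SIO for descriptors, ChEBI for the drug role and oligomer
classes, PRO for proteins, BFO for the material-entity root).  Where the
meaning is only implied by the relational schema — endpoint names,
standardized values, units, the assay/target wiring — terms stay in the
legacy `chembl:` namespace (`http://rdf.farmbio.uu.se/chembl/onto/#`) and
literals stay plain strings.  Leaving those semantics undefined is a
choice: inferring intent that the primary literature never specified
would bake errors into the graph.

Specific decisions worth spelling out:

* **Class-style molecules.**  CHEMINF models chemical entities as
  classes; identity links to other molecule databases therefore use
  `owl:equivalentClass`, and the drug role must be attached as a
  subclass-of-restriction (`has-role some CHEBI_23888`) rather than an
  instance assertion.  Only database-flagged approved drugs get the role:
  a compound is a drug only in the context of being used as one.
* **Protein class IRIs.**  Molecule-side protein drugs subclass
  `PR_000000001`; target-side proteins subclass `PR_0000001`.  The two
  spellings are kept distinct deliberately, following the published
  pattern for each entity kind; both are configurable in
  `chembl_vocab()` if a deployment wants to unify them.
* **`CELL` molecules** have no published superclass mapping; this package
  maps them to a `chembl:CELL` class rooted in `bfo:MaterialEntity`, so
  the material-entity census still covers every converted molecule.
* **Common target class.**  All targets are counted under a shared
  `chembl:Target`: protein targets via `rdfs:subClassOf` (class-style),
  every other category via `rdf:type`.  The count query is the union of
  both forms, mirroring a SPARQL `UNION`.
* **Elided predicate spellings.**  The exact predicates wiring
  activities to assays/molecules (`chembl:onAssay`, `chembl:forMolecule`)
  and constructs to targets/scores (`chembl:hasTargetDescription`,
  `chembl:hasTarget`, `chembl:hasConfScore`), the CiTO property
  (`cito:citesAsDataSource`), and the SIO attribute/value pair
  (`SIO_000008`/`SIO_000300`) are centralized in `chembl_vocab()` with
  documented defaults, so alternative spellings can be swapped in without
  touching the converter.
* **Blank nodes** are used for target-confidence constructs, descriptor
  nodes and role restrictions — no IRI scheme exists for them — with
  labels derived deterministically from record identifiers.  Equality of
  converted output is therefore tested by graph isomorphism, not by
  string comparison.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `uri_policy(mode)` | `"canonical"` | `linkedchemistry.info/chembl/...` IRIs; `"legacy"` rewrites onto `data.kasabi.com/dataset/chembl-rdf/...` |
| `max_uri_length` | 2000 chars | cap on InChI-derived IRIs; endpoint software commonly rejects very long URIs, and 2000 is a conservative interoperable bound |
| `inchi_uri_base` | `http://rdf.openmolecules.net/?InChI=` | base of InChI identity links |
| percent-encoding safe set | unreserved + `=/?,()` | keeps InChI layer separators readable in IRIs while remaining RFC 3986-valid |
| `link_rules()` | exactMatch / equivalentClass / sameAs / exactMatch | graded link predicates per external resource; Bio2RDF defaults to `skos:exactMatch` (record-level identity without OWL entailment risk) |
| `selectivity_query(min_confidence)` | `NULL` | confidence floor on assay-target mappings; ignored by default to return the largest possible set |

Thresholds in the selectivity query are strict (`< threshold_a`,
`> threshold_b`), and a molecule qualifies existentially: any one
measurement per side suffices, matching the join semantics of the
equivalent SPARQL query.  Results are deduplicated to distinct molecules
(not molecule–measurement pairs).  Units must match the query string
exactly; a differing unit on an otherwise-qualifying activity raises an
error rather than silently filtering, because nM/µg·mL⁻¹ conversion is
out of scope.

## What the synthetic generator emulates — and what it does not

`generate_snapshot()` is a pure function of its `fixture_config()`
(including the seed).  The desk-scale defaults — 300 molecules, 40
targets, 200 assays, 1200 activities, 60 documents — emulate the
*structure* of a ChEMBL 13-style release:

* molecule types dominated by small molecules with a tail of biologics
  and cells; ~95 % of small molecules carry SMILES/InChI/InChIKey and
  ACD/Labs-style computed properties;
* an endpoint mix led by Potency (43 %) and IC50 (13 %) with MIC,
  Inhibition and Ki in the few-percent range, log-normal standardized
  values, and string units;
* a typeless-assay fraction of 0.025, leaving exactly
  `ceiling(0.025 × 200) = 5` untyped assays — the same absolute handful
  the real release carries;
* the sentinel unpublished document, present by default;
* a 2 % fraction of molecules whose InChI exceeds the default IRI length
  cap, so the link census has something to exclude;
* 5 % approved drugs (deliberately above the real-world share of roughly
  1 %, so desk-scale fixtures reliably contain a few).

Planted selectivity adds two protein targets (default accessions P24941
and P11802, the kinase pair of the classic use case), two dedicated
binding assays mapped only to them, and `k` molecules measured at 10 nM
on A and 1000 nM on B.  Background assay-target assignments avoid the
planted targets, so an exhaustive relational filter provably returns
exactly the planted set — that construction is what the oracle-equivalence
tests rely on.

What the generator does *not* emulate: chemically valid structures (the
InChI/SMILES strings are syntactically shaped, not real molecules — they
are synthetic and labelled as such), the long tail of five-thousand-plus
endpoint types, skewed per-document activity counts, curation noise such
as dangling keys (injected explicitly in tests instead), and full-scale
cardinalities.  Passing tests therefore demonstrate the correctness of
the conversion logic, the delta structure of the counts, and the query
semantics — not performance or robustness on the real multi-million-row
dump, for which the loader accepts the same table layout via TSV or
SQLite.

## Numerical and serialization choices

* Standardized values are `xsd:double` literals (generated values are
  rounded to three decimals so delimited-text round trips are exact);
  confidence scores `xsd:integer`; flags `xsd:boolean`; endpoint names,
  units and relations plain literals.
* Turtle output binds the full namespace table, groups by subject, and
  only shortens IRIs whose local name is conservatively prefix-safe;
  everything else stays a full IRI.  Literal escaping (quotes, newlines,
  backslashes, non-ASCII) is handled centrally in the serializer — a
  class of bug that historically plagued string-built RDF exporters.
* N-Triples output is sorted, hence byte-deterministic and diff-friendly.
* Graph isomorphism uses iterated structural hashing of blank nodes with
  a bounded backtracking fallback for symmetric groups; ground triples
  are compared as sets.
* The dereferencing layer returns a bounded description: all outgoing
  triples, expanded transitively through blank nodes, so constructs and
  descriptor nodes travel whole.  Content negotiation maps RDF media
  types to Turtle/N-Triples and everything else (including no header) to
  a plain HTML triple table; RDFa output is out of scope.
* The proxy URL translator is bijective per resource kind; the path
  segment → namespace mapping is a configurable alias table (the
  historical `article/` path resolves into the activity namespace).

## Degenerate inputs

Empty tables convert to empty graphs; an empty fixture directory with
headers loads cleanly.  Missing table files, dangling foreign keys
(reported with the offending identifiers), confidence scores outside
0–9, an InChIKey without an InChI, and a repeated sentinel document are
all fatal at load/validation time.  A malformed InChI is an error in
`inchi_uri()`, distinct from the `NA` returned for an overlong one.

## Known limitations

* Endpoint types and units are plain literals: no reasoning over related
  endpoints (IC50 vs Ki) or unit conversion is possible until they are
  mapped to ontologies (BioAssay Ontology, QUDT are the obvious
  candidates).
* The validation counts entities per class; it cannot detect value-level
  corruption that preserves cardinalities.
* Conversion is vectorized in memory rather than streamed; desk-scale
  runs take seconds, but a full release dump needs the memory to hold
  its graph (the tibble representation is roughly proportional to the
  triple count).
* The HTTP layer is a minimal wrapper over the pure request handler; it
  does not implement the SPARQL protocol — the SPARQL templates exported
  by `sparql_selectivity()`, `sparql_citation_count()` and
  `sparql_count()` are intended for external endpoints hosting the
  triples.
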