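# chemblrdf

Bioactivity databases following the ChEMBL relational schema hold millions
of measurements — a molecule, tested in an assay, against a target,
reported in a paper.  Locked inside a SQL dump, that knowledge is hard to
combine with the rest of the life-sciences linked-data cloud.  `chemblrdf`
converts such a relational snapshot into RDF triples built on community
ontologies, so the data can be published as dereferencable linked data,
cross-linked to external databases, validated by counting, and queried.

The package is aimed at cheminformaticians and data engineers who need to
triplify ChEMBL-style relational data, and at method developers who want a
small, fully testable model of that conversion.

## The conversion model

Every record type has a fixed triple pattern:

* **Molecules are classes, not instances.**  A molecule IRI gets
  `rdfs:subClassOf` its type-specific superclass — small molecules the
  CHEMINF chemical-entity class (`CHEMINF_000000`), protein/peptide/antibody
  drugs the PRO protein class (`PR_000000001`), oligosaccharides and
  oligonucleotides their ChEBI classes (`CHEBI_50699`, `CHEBI_7754`) — and
  everything is rooted in the BFO 1.1 `MaterialEntity` class.
* **Approved drugs carry a drug *role*, not a drug type**: a
  subclass-of-restriction `has-role some CHEBI_23888` is attached only to
  molecules the database flags as approved.
* **Identifiers and properties use the CHEMINF/SIO descriptor pattern**:
  SMILES, InChI, InChIKey and computed properties (logP, H-bond counts)
  become typed descriptor nodes carrying a value and, where known, the
  computing software (e.g. ACD/Labs).
* **Activities are instances** (`chembl:Activity`) exposing the endpoint
  name as a plain literal (`chembl:type "IC50"`), only the *standardized*
  value (typed double) with its relation and unit string, links to assay
  and molecule, and a CiTO `citesAsDataSource` link to the source document.
* **Assays** require a defined assay type — untyped assay rows produce no
  triples.  Each assay-to-target assignment becomes a blank construct node
  pairing the target with its integer confidence score (9 = direct single
  protein target, 0 = uncurated).
* **Targets**: protein targets are class-style (`rdfs:subClassOf
  pro:PR_0000001`); all other categories (cell line, organism, tissue, …,
  including the explicit `UNCHECKED`/`UNKNOWN` types) are instances of
  their `chembl:` category.
* **Documents** become `bibo:Article` resources with PMID/DOI; the
  sentinel `doc_id = -1` ("unpublished") is skipped.
* **Link-outs are graded**: ChemSpider mappings use `skos:exactMatch`,
  InChI-based OpenMolecules links `owl:equivalentClass` (class identity),
  CrossRef DOI links `owl:sameAs`, Bio2RDF UniProt/PubMed links
  `skos:exactMatch` — never a stronger predicate than the relation
  justifies.  InChI-based IRIs are only minted when they fit under a
  configurable length cap.

Because the conversion drops exactly two kinds of rows (untyped assays,
the sentinel document), counting entities per class in the graph must
reproduce the source-table counts with a known delta structure — that
count-based validation is a first-class operation here, as is the classic
application query: find molecules binding protein A with high affinity
(e.g. IC50 < 50 nM) and protein B with low affinity (> 200 nM).

## Worked example

```r
library(chemblrdf)

cfg  <- fixture_config(seed = 42, planted_selectivity = plant_selectivity(k = 7))
snap <- generate_snapshot(cfg)
snap
#> <chembl_snapshot>
#>   molecules        300 rows
#>   properties       732 rows
#>   assays           200 rows
#>   assay2target     230 rows
#>   targets           40 rows
#>   activities      1200 rows
#>   docs              60 rows

graph <- graph_union(triplify_snapshot(snap), linkout_graph(snap))
nrow(graph)
#> [1] 18083

validate_conversion(snap, graph)
#> # Conversion validation: PASS
#> # A tibble: 5 x 6
#>   quantity          source_count graph_count delta expected_delta ok
#> 1 targets                     40          40     0              0 TRUE
#> 2 material_entities          300         300     0              0 TRUE
#> 3 assays                     200         195     5              5 TRUE
#> 4 activities                1200        1200     0              0 TRUE
#> 5 articles                    60          59     1              1 TRUE
```

The five untyped assays and the sentinel document account for the only
non-zero deltas — any other delta would flag a conversion defect.  The
planted selective binders come back from the graph-level query (targets
addressed by UniProt accession through the Bio2RDF link-outs):

```r
q <- selectivity_query("P24941", "P11802", activity_type = "IC50",
                       threshold_a = 50, threshold_b = 200, units = "nM")
selective_binders(graph, q)
#> # A tibble: 7 x 1
#>   molecule
#> 1 http://linkedchemistry.info/chembl/molecule/ChEMBL184148
#> ...
```

Graphs serialize to Turtle/N-Triples and every minted IRI dereferences to
a bounded description with content negotiation:

```r
write_rdf(graph, "snapshot.nt")
handle_request(graph, mint_uri("activity", "a300001"), "text/turtle")$status
#> [1] 200
```

A command-line wrapper is installed at `exec/chemblrdf` (subcommands
`make-fixture`, `convert`, `validate`, `stats`, `query-selectivity`,
`query-citations`, `serve`).

When run against the real ChEMBL 13 dump, the validation report prints the
release statistics as reference values; `chembl13_reference_counts()`
holds them (8,845 targets; 1,143,682 molecules; 6,933,068 activities;
617,676 of 617,681 assays; 44,681 of 44,682 documents).

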