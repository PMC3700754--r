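#' Link-out rules
#'
#' Cross-database links use predicates graded by increasing strength of
#' implication: `rdfs:seeAlso` ("you may also be interested in"),
#' `skos:exactMatch`, `owl:equivalentClass`, and `owl:sameAs` ("identical;
#' all properties apply to both").  ChemSpider compound mappings use
#' `skos:exactMatch`; OpenMolecules InChI links use `owl:equivalentClass`
#' (molecules are classes); CrossRef DOI links use `owl:sameAs`; Bio2RDF
#' record links (UniProt for protein targets, PubMed for documents) default
#' to `skos:exactMatch` -- record-level identity without OWL entailment
#' risk.  Templates are `sprintf`-style with one `%s` slot and are
#' configurable, since third-party hosts drift.
#'
#' @param overrides Optional data frame with columns `target`, `predicate`,
#'   `template` replacing rows of the default table.
#' @param vocab A [chembl_vocab()] supplying the graded predicate IRIs.
#' @return Tibble with columns `target`, `predicate`, `template`.
#' @export
link_rules <- function(overrides = NULL, vocab = chembl_vocab()) {
  rules <- tibble::tibble(
    target = c("ChemSpider", "OpenMolecules", "Bio2RDF-UniProt",
               "Bio2RDF-PubMed", "CrossRef"),
    predicate = c(vocab$exact_match, vocab$equivalent_class,
                  vocab$exact_match, vocab$exact_match, vocab$same_as),
    template = c("http://rdf.chemspider.com/%s", "",
                 "http://bio2rdf.org/uniprot:%s",
                 "http://bio2rdf.org/pubmed:%s",
                 "http://dx.doi.org/%s")
  )
  if (!is.null(overrides)) {
    overrides <- tibble::as_tibble(overrides)
    i <- match(overrides$target, rules$target)
    if (anyNA(i)) stop("unknown link rule target: ",
                       paste(overrides$target[is.na(i)], collapse = ", "),
                       call. = FALSE)
    rules[i, names(overrides)] <- overrides
  }
  graded <- c(vocab$see_also, vocab$exact_match, vocab$equivalent_class,
              vocab$same_as)
  bad <- setdiff(rules$predicate, graded)
  if (length(bad)) {
    stop("link predicate is not one of the four graded predicates: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rules
}

#' Read link rules from a delimited file
#'
#' Three tab-separated columns: target, predicate IRI, IRI template.
#'
#' @param path File path.
#' @param vocab A [chembl_vocab()].
#' @return Tibble of rules (defaults overridden by the file's rows).
#' @export
read_link_rules <- function(path, vocab = chembl_vocab()) {
  link_rules(readr::read_tsv(path, col_names = c("target", "predicate",
                                                 "template"),
                             col_types = "ccc", progress = FALSE),
             vocab = vocab)
}

.rule <- function(rules, target) {
  r <- rules[rules$target == target, ]
  if (nrow(r) != 1) stop("no link rule for ", target, call. = FALSE)
  r
}

#' Link a molecule to its ChemSpider record
#'
#' One `skos:exactMatch` triple to the ChemSpider resource, plus a CHEMINF
#' descriptor node carrying the CSID value itself.  CSID-to-molecule
#' mappings are an input table (provided by the mapping data release), not
#' computed by structure matching.
#'
#' @param molecule One-row data frame (or named list) of molecule columns.
#' @param csid Positive integer ChemSpider identifier.
#' @param policy A [uri_policy()].
#' @param vocab A [chembl_vocab()].
#' @param rules A [link_rules()] table.
#' @return An `rdf_graph`.
#' @export
link_chemspider <- function(molecule, csid, policy = uri_policy(),
                            vocab = chembl_vocab(policy$namespaces),
                            rules = link_rules(vocab = vocab)) {
  m <- .as_row(molecule)
  csid <- as.integer(csid)
  if (any(is.na(csid) | csid <= 0L)) {
    stop("csid must be a positive integer", call. = FALSE)
  }
  r <- .rule(rules, "ChemSpider")
  iri <- mint_uri("molecule", m$chembl_id, policy)
  rows <- c(
    list(triples_iri(iri, r$predicate, sprintf(r$template, csid))),
    .descriptor_rows(iri, paste0("_:desc_", m$chembl_id, "_csid"),
                     vocab$desc_csid, csid, vocab,
                     datatype = vocab$xsd_integer)
  )
  .graph(rows, policy)
}

.link_openmolecules_tbl <- function(molecules, policy, vocab, rules) {
  r <- .rule(rules, "OpenMolecules")
  has <- which(!is.na(molecules$inchi))
  if (length(has) == 0) return(list())
  ext <- inchi_uri(molecules$inchi[has], policy)
  ok <- which(!is.na(ext))
  if (length(ok) == 0) return(list())
  list(triples_iri(
    mint_uri("molecule", molecules$chembl_id[has][ok], policy),
    r$predicate, ext[ok]
  ))
}

#' Link a molecule to OpenMolecules RDF via its InChI
#'
#' `owl:equivalentClass` (molecules are classes, so identity between
#' records is class equivalence) to the InChI-based IRI.  Empty when the
#' molecule has no InChI or the InChI-based IRI exceeds the policy's
#' length cap.
#'
#' @inheritParams link_chemspider
#' @return An `rdf_graph`.
#' @export
link_openmolecules <- function(molecule, policy = uri_policy(),
                               vocab = chembl_vocab(policy$namespaces),
                               rules = link_rules(vocab = vocab)) {
  .graph(.link_openmolecules_tbl(.as_row(molecule), policy, vocab, rules),
         policy)
}

#' Link a protein target or document to Bio2RDF
#'
#' Protein targets with a UniProt accession link to the Bio2RDF UniProt
#' resource; documents with a PMID link to the Bio2RDF PubMed resource.
#' Entities not meeting those preconditions yield an empty graph (not an
#' error).
#'
#' @param entity One-row data frame (or named list): a target (has
#'   `target_id`) or a document (has `doc_id`).
#' @inheritParams link_chemspider
#' @return An `rdf_graph`.
#' @export
link_bio2rdf <- function(entity, policy = uri_policy(),
                         vocab = chembl_vocab(policy$namespaces),
                         rules = link_rules(vocab = vocab)) {
  e <- .as_row(entity)
  if ("target_id" %in% names(e)) {
    ok <- e$target_type == "PROTEIN" & !is.na(e$uniprot_accession)
    if (!any(ok)) return(.graph(list(), policy))
    r <- .rule(rules, "Bio2RDF-UniProt")
    return(.graph(list(triples_iri(
      mint_uri("target", e$target_id[ok], policy),
      r$predicate, sprintf(r$template, e$uniprot_accession[ok])
    )), policy))
  }
  if ("doc_id" %in% names(e)) {
    ok <- !is.na(e$pmid) & e$doc_id != -1L
    if (!any(ok)) return(.graph(list(), policy))
    r <- .rule(rules, "Bio2RDF-PubMed")
    return(.graph(list(triples_iri(
      mint_uri("resource", paste0("r", e$doc_id[ok]), policy),
      r$predicate, sprintf(r$template, e$pmid[ok])
    )), policy))
  }
  stop("entity must be a target or document record", call. = FALSE)
}

.link_crossref_tbl <- function(docs, policy, vocab, rules) {
  ok <- which(!is.na(docs$doi) & docs$doc_id != -1L)
  if (length(ok) == 0) return(list())
  r <- .rule(rules, "CrossRef")
  # DOIs keep their structural characters readable; anything else unsafe
  # in an IRI path is percent-encoded (and decodes back to the DOI)
  esc <- percent_encode(docs$doi[ok], safe = "()/:")
  list(triples_iri(
    mint_uri("resource", paste0("r", docs$doc_id[ok]), policy),
    r$predicate, sprintf(r$template, esc)
  ))
}

#' Link a document to CrossRef via its DOI
#'
#' One `owl:sameAs` triple from the document resource to the
#' `http://dx.doi.org/` IRI of the DOI; empty graph when the DOI is absent.
#'
#' @param doc One-row data frame (or named list) of document columns.
#' @inheritParams link_chemspider
#' @return An `rdf_graph`.
#' @export
link_crossref <- function(doc, policy = uri_policy(),
                          vocab = chembl_vocab(policy$namespaces),
                          rules = link_rules(vocab = vocab)) {
  .graph(.link_crossref_tbl(.as_row(doc), policy, vocab, rules), policy)
}

#' Read a CSID mapping file
#'
#' Two tab-separated columns: `chembl_id`, `csid`.
#'
#' @param path File path.
#' @return Tibble with columns `chembl_id` and `csid`.
#' @export
read_csid_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(chembl_id = "c", csid = "i"),
                  progress = FALSE)
}

#' Generate all link-out triples for a snapshot
#'
#' ChemSpider links for every molecule in the CSID mapping, OpenMolecules
#' links for every molecule with a usable InChI, Bio2RDF links for protein
#' targets with accessions and documents with PMIDs, and CrossRef links
#' for documents with DOIs.
#'
#' @param snapshot A `chembl_snapshot`.
#' @param csid_map Optional tibble (`chembl_id`, `csid`) of ChemSpider
#'   mappings.
#' @inheritParams link_chemspider
#' @return An `rdf_graph` of all link triples.
#' @export
linkout_graph <- function(snapshot, csid_map = NULL,
                          policy = uri_policy(),
                          vocab = chembl_vocab(policy$namespaces),
                          rules = link_rules(vocab = vocab)) {
  rows <- .link_openmolecules_tbl(snapshot$molecules, policy, vocab, rules)
  rows <- c(rows, .link_crossref_tbl(snapshot$docs, policy, vocab, rules))

  tg <- snapshot$targets
  ok <- which(tg$target_type == "PROTEIN" & !is.na(tg$uniprot_accession))
  if (length(ok)) {
    r <- .rule(rules, "Bio2RDF-UniProt")
    rows <- c(rows, list(triples_iri(
      mint_uri("target", tg$target_id[ok], policy),
      r$predicate, sprintf(r$template, tg$uniprot_accession[ok])
    )))
  }
  dc <- snapshot$docs
  ok <- which(!is.na(dc$pmid) & dc$doc_id != -1L)
  if (length(ok)) {
    r <- .rule(rules, "Bio2RDF-PubMed")
    rows <- c(rows, list(triples_iri(
      mint_uri("resource", paste0("r", dc$doc_id[ok]), policy),
      r$predicate, sprintf(r$template, dc$pmid[ok])
    )))
  }
  if (!is.null(csid_map) && nrow(csid_map) > 0) {
    if (any(is.na(csid_map$csid) | csid_map$csid <= 0)) {
      stop("csid must be a positive integer", call. = FALSE)
    }
    known <- csid_map[csid_map$chembl_id %in% snapshot$molecules$chembl_id, ]
    if (nrow(known)) {
      r <- .rule(rules, "ChemSpider")
      iri <- mint_uri("molecule", known$chembl_id, policy)
      rows <- c(rows,
                list(triples_iri(iri, r$predicate,
                                 sprintf(r$template, known$csid))),
                .descriptor_rows(iri,
                                 paste0("_:desc_", known$chembl_id, "_csid"),
                                 vocab$desc_csid, known$csid, vocab,
                                 datatype = vocab$xsd_integer))
    }
  }
  .graph(rows, policy)
}
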