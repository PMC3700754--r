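#' @title Relational-to-RDF conversion
#' @description
#' Each converter below maps one record type onto its triple pattern.
#' Molecules and protein targets are modelled as ontology *classes*
#' (`rdfs:subClassOf` their type-specific superclass, everything rooted in
#' the BFO material-entity class), while assays, activities and documents
#' are plain *instances* (`rdf:type`).  Chemical identifiers and computed
#' properties become CHEMINF descriptor nodes carrying a value and, where
#' known, software provenance.  Two exclusion rules apply: assays without a
#' defined assay type and the sentinel document `doc_id = -1` produce no
#' triples at all.
#' @name triplify
NULL

# superclass of the molecule class for each molecule type
.molecule_superclass <- function(molecule_type, vocab) {
  map <- c(
    SMALL_MOLECULE = vocab$class_chemical_entity,
    PROTEIN = vocab$class_protein_mol,
    PEPTIDE = vocab$class_protein_mol,
    ANTIBODY = vocab$class_protein_mol,
    OLIGOSACCHARIDE = vocab$class_oligosaccharide,
    OLIGONUCLEOTIDE = vocab$class_oligonucleotide,
    CELL = vocab$class_cell
  )
  out <- unname(map[molecule_type])
  if (any(is.na(out))) {
    stop("unknown molecule_type: ",
         paste(unique(molecule_type[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

.as_row <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    tibble::as_tibble(x)
  } else {
    tibble::as_tibble(x[!vapply(x, is.null, logical(1))])
  }
}

.graph <- function(rows, policy) {
  rdf_graph(dplyr::bind_rows(rows), namespaces = policy$namespaces)
}

# ---- molecules --------------------------------------------------------------

.triplify_molecules_tbl <- function(molecules, policy, vocab) {
  if (nrow(molecules) == 0) return(list())
  iri <- mint_uri("molecule", molecules$chembl_id, policy)
  super <- .molecule_superclass(molecules$molecule_type, vocab)
  rows <- list(
    triples_iri(iri, vocab$subclass_of, super),
    # root the type-specific superclasses in the material-entity class
    triples_iri(unique(super), vocab$subclass_of, vocab$class_material_entity)
  )
  named <- !is.na(molecules$pref_name)
  if (any(named)) {
    rows <- c(rows, list(
      triples_lit(iri[named], vocab$label, molecules$pref_name[named])
    ))
  }
  with_syn <- which(!is.na(molecules$synonyms))
  if (length(with_syn) > 0) {
    syn <- strsplit(molecules$synonyms[with_syn], "|", fixed = TRUE)
    rows <- c(rows, list(
      triples_lit(rep(iri[with_syn], lengths(syn)), vocab$label,
                  unlist(syn))
    ))
  }
  rows
}

#' Convert a molecule record into class-style triples
#'
#' The molecule IRI subclasses its type-specific superclass (small
#' molecules the CHEMINF chemical-entity class, protein-like molecules the
#' PRO protein class, oligosaccharides/oligonucleotides their ChEBI
#' classes), which in turn subclasses the BFO material-entity root.
#' Preferred name and synonyms become labels.
#'
#' @param molecule One-row data frame (or named list) with the molecule
#'   columns of a snapshot.
#' @param policy A [uri_policy()].
#' @param vocab A [chembl_vocab()].
#' @return An `rdf_graph`.
#' @export
triplify_molecule <- function(molecule, policy = uri_policy(),
                              vocab = chembl_vocab(policy$namespaces)) {
  .graph(.triplify_molecules_tbl(.as_row(molecule), policy, vocab), policy)
}

.attach_drug_role_tbl <- function(molecules, policy, vocab) {
  appr <- molecules[which(molecules$approved_drug), ]
  if (nrow(appr) == 0) return(list())
  iri <- mint_uri("molecule", appr$chembl_id, policy)
  bn <- paste0("_:role_", appr$chembl_id)
  list(
    triples_iri(iri, vocab$subclass_of, bn),
    triples_iri(bn, vocab$rdf_type, vocab$class_restriction),
    triples_iri(bn, vocab$on_property, vocab$has_role),
    triples_iri(bn, vocab$some_values, vocab$class_drug_role)
  )
}

#' Attach the drug role to an approved drug
#'
#' Molecules are classes, so the role is asserted as a subclass-of
#' restriction (`has-role some drug-role`), using the ChEBI drug-role term.
#' Non-approved molecules yield an empty graph: an entity is only a drug in
#' the context of being used as a medication, and the conversion restricts
#' the role to database-flagged approved drugs.  The rule depends only on
#' the approval flag, never on the molecule type.
#'
#' @inheritParams triplify_molecule
#' @return An `rdf_graph` (empty unless `approved_drug` is true).
#' @export
attach_drug_role <- function(molecule, policy = uri_policy(),
                             vocab = chembl_vocab(policy$namespaces)) {
  .graph(.attach_drug_role_tbl(.as_row(molecule), policy, vocab), policy)
}

.descriptor_rows <- function(mol_iri, bnode, class_iri, value, vocab,
                             datatype = NA_character_, software = NULL) {
  rows <- list(
    triples_iri(mol_iri, vocab$has_attribute, bnode),
    triples_iri(bnode, vocab$rdf_type, class_iri),
    triples_lit(bnode, vocab$has_value, value, datatype = datatype)
  )
  if (!is.null(software)) {
    keep <- !is.na(software)
    if (any(keep)) {
      rows <- c(rows, list(
        triples_lit(bnode[keep], vocab$calculated_by, software[keep])
      ))
    }
  }
  rows
}

.triplify_descriptors_tbl <- function(molecules, properties, policy, vocab) {
  rows <- list()
  if (nrow(molecules) > 0) {
    iri <- mint_uri("molecule", molecules$chembl_id, policy)
    for (field in c("smiles", "inchi", "inchikey")) {
      has <- which(!is.na(molecules[[field]]))
      if (length(has) == 0) next
      cls <- switch(field, smiles = vocab$desc_smiles,
                    inchi = vocab$desc_inchi, inchikey = vocab$desc_inchikey)
      rows <- c(rows, .descriptor_rows(
        iri[has], paste0("_:desc_", molecules$chembl_id[has], "_", field),
        cls, molecules[[field]][has], vocab
      ))
    }
  }
  if (!is.null(properties) && nrow(properties) > 0) {
    if (any(!is.finite(properties$value))) {
      stop("non-numeric property value for ",
           paste(properties$chembl_id[!is.finite(properties$value)],
                 collapse = ", "), call. = FALSE)
    }
    rows <- c(rows, .descriptor_rows(
      mint_uri("molecule", properties$chembl_id, policy),
      paste0("_:desc_", properties$chembl_id, "_prop_",
             percent_encode(properties$property)),
      .property_descriptor_class(properties$property, vocab,
                                 policy$namespaces),
      properties$value, vocab,
      datatype = vocab$xsd_double,
      software = properties$software
    ))
  }
  rows
}

#' Convert chemical identifiers and properties to CHEMINF descriptor nodes
#'
#' One descriptor node per present identifier (SMILES, InChI, InChIKey) and
#' per numeric property row.  Each node is typed by its descriptor class,
#' attached to the molecule with the SIO has-attribute property, carries
#' its value via SIO has-value, and records the computing software (e.g.
#' ACD/Labs for the shipped logP) when known.  Absent fields yield no node.
#'
#' @inheritParams triplify_molecule
#' @param properties Property rows (`chembl_id`, `property`, `value`,
#'   `software`) for this molecule, or `NULL`.
#' @return An `rdf_graph`.
#' @export
triplify_descriptors <- function(molecule, policy = uri_policy(),
                                 vocab = chembl_vocab(policy$namespaces),
                                 properties = NULL) {
  .graph(.triplify_descriptors_tbl(.as_row(molecule), properties, policy,
                                   vocab), policy)
}

# ---- activities -------------------------------------------------------------

.triplify_activities_tbl <- function(activities, policy, vocab) {
  if (nrow(activities) == 0) return(list())
  a <- activities
  iri <- mint_uri("activity", a$activity_id, policy)
  rows <- list(
    triples_iri(iri, vocab$rdf_type, vocab$class_activity),
    triples_lit(iri, vocab$activity_type, a$activity_type),
    triples_iri(iri, vocab$on_assay, mint_uri("assay", a$assay_id, policy)),
    triples_iri(iri, vocab$for_molecule,
                mint_uri("molecule", a$chembl_id, policy))
  )
  hv <- which(!is.na(a$std_value))
  if (length(hv)) {
    rows <- c(rows, list(triples_lit(iri[hv], vocab$standard_value,
                                     a$std_value[hv],
                                     datatype = vocab$xsd_double)))
  }
  hu <- which(!is.na(a$std_units))
  if (length(hu)) {
    rows <- c(rows, list(triples_lit(iri[hu], vocab$standard_units,
                                     a$std_units[hu])))
  }
  hr <- which(!is.na(a$relation))
  if (length(hr)) {
    rows <- c(rows, list(triples_lit(iri[hr], vocab$standard_relation,
                                     a$relation[hr])))
  }
  cited <- which(!is.na(a$doc_id) & a$doc_id != -1L)
  if (length(cited)) {
    rows <- c(rows, list(triples_iri(
      iri[cited], vocab$citation,
      mint_uri("resource", paste0("r", a$doc_id[cited]), policy)
    )))
  }
  rows
}

#' Convert an activity record
#'
#' The activity resource is typed `chembl:Activity` and carries the
#' endpoint name as a plain literal (`chembl:type`), the *standardized*
#' value as a typed double with its relation and unit string (units stay
#' plain literals; no unit ontology), links to its assay and molecule, and
#' a CiTO data-source citation of the originating document.  Original
#' literature values are never emitted, only the standardized ones.
#'
#' @param activity One-row data frame (or named list) of activity columns.
#' @inheritParams triplify_molecule
#' @return An `rdf_graph`.
#' @export
triplify_activity <- function(activity, policy = uri_policy(),
                              vocab = chembl_vocab(policy$namespaces)) {
  .graph(.triplify_activities_tbl(.as_row(activity), policy, vocab), policy)
}

# ---- assays -----------------------------------------------------------------

.triplify_assays_tbl <- function(assays, assay2target, policy, vocab) {
  typed <- assays[!is.na(assays$assay_type), ]
  if (nrow(typed) == 0) return(list())
  iri <- mint_uri("assay", typed$assay_id, policy)
  rows <- list(
    triples_iri(iri, vocab$rdf_type, vocab$class_assay),
    triples_lit(iri, vocab$assay_type, typed$assay_type)
  )
  hd <- which(!is.na(typed$description))
  if (length(hd)) {
    rows <- c(rows, list(triples_lit(iri[hd], vocab$description,
                                     typed$description[hd])))
  }
  cited <- which(!is.na(typed$doc_id) & typed$doc_id != -1L)
  if (length(cited)) {
    rows <- c(rows, list(triples_iri(
      iri[cited], vocab$citation,
      mint_uri("resource", paste0("r", typed$doc_id[cited]), policy)
    )))
  }
  at <- assay2target[assay2target$assay_id %in% typed$assay_id, ]
  if (nrow(at) > 0) {
    if (any(is.na(at$confidence_score) | at$confidence_score < 0L |
            at$confidence_score > 9L)) {
      stop("confidence score outside 0-9 for assay ",
           paste(unique(at$assay_id[is.na(at$confidence_score) |
                                      at$confidence_score < 0 |
                                      at$confidence_score > 9]),
                 collapse = ", "), call. = FALSE)
    }
    a_iri <- mint_uri("assay", at$assay_id, policy)
    bn <- paste0("_:td_", at$assay_id, "_", at$target_id)
    rows <- c(rows, list(
      triples_iri(a_iri, vocab$has_target_description, bn),
      triples_iri(bn, vocab$has_target,
                  mint_uri("target", at$target_id, policy)),
      triples_lit(bn, vocab$has_conf_score, at$confidence_score,
                  datatype = vocab$xsd_integer)
    ))
    hr <- which(!is.na(at$relationship_type))
    if (length(hr)) {
      rows <- c(rows, list(triples_lit(bn[hr], vocab$relationship_type,
                                       at$relationship_type[hr])))
    }
    for (fl in c("multi_flag", "complex_flag")) {
      hf <- which(!is.na(at[[fl]]))
      if (length(hf)) {
        rows <- c(rows, list(triples_lit(
          bn[hf], vocab[[fl]],
          tolower(as.character(at[[fl]][hf])),
          datatype = vocab$xsd_boolean
        )))
      }
    }
  }
  rows
}

#' Convert an assay record and its target assignments
#'
#' An assay without a defined assay type is skipped entirely (empty graph):
#' triple generation requires the type.  Otherwise the assay is typed
#' `chembl:Assay` with its assay type and description, and each target
#' assignment becomes an intermediate blank construct node pairing the
#' target IRI with the integer confidence score -- the score qualifies the
#' assay-to-target mapping, so it cannot live on the assay itself -- plus
#' the relationship type and multi/complex flags when present.  The assay
#' also cites its source document (CiTO), except the sentinel.
#'
#' @param assay One-row data frame (or named list) of assay columns.
#' @param assignments Assignment rows for this assay (may be empty).
#' @inheritParams triplify_molecule
#' @return An `rdf_graph`.
#' @export
triplify_assay <- function(assay, assignments = NULL,
                           policy = uri_policy(),
                           vocab = chembl_vocab(policy$namespaces)) {
  if (is.null(assignments)) assignments <- .empty_tables()$assay2target
  .graph(.triplify_assays_tbl(.as_row(assay), tibble::as_tibble(assignments),
                              policy, vocab), policy)
}

# ---- targets ----------------------------------------------------------------

.triplify_targets_tbl <- function(targets, policy, vocab) {
  if (nrow(targets) == 0) return(list())
  bad <- setdiff(unique(targets$target_type), target_types())
  if (length(bad)) {
    stop("unknown target_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  iri <- mint_uri("target", targets$target_id, policy)
  prot <- targets$target_type == "PROTEIN"
  rows <- list()
  if (any(prot)) {
    rows <- c(rows, list(
      # protein targets are class-style, like the molecules
      triples_iri(iri[prot], vocab$subclass_of, vocab$class_protein_target),
      triples_iri(iri[prot], vocab$subclass_of, vocab$class_target)
    ))
  }
  if (any(!prot)) {
    cls <- .target_type_class(targets$target_type[!prot], policy$namespaces)
    rows <- c(rows, list(
      # non-protein categories (incl. UNCHECKED/UNKNOWN) are explicit
      # types: a closed-world reading of the source vocabulary
      triples_iri(iri[!prot], vocab$rdf_type, cls),
      triples_iri(iri[!prot], vocab$rdf_type, vocab$class_target)
    ))
  }
  hl <- which(!is.na(targets$label))
  if (length(hl)) {
    rows <- c(rows, list(triples_lit(iri[hl], vocab$label,
                                     targets$label[hl])))
  }
  rows
}

#' Convert a target record
#'
#' Protein targets are emitted class-style (subclass of the PRO protein
#' class and of the common `chembl:Target` class); every other category --
#' including the explicit UNCHECKED and UNKNOWN types -- gets an
#' `rdf:type` to its `chembl:` category plus `chembl:Target`.
#'
#' @param target One-row data frame (or named list) of target columns.
#' @inheritParams triplify_molecule
#' @return An `rdf_graph`.
#' @export
triplify_target <- function(target, policy = uri_policy(),
                            vocab = chembl_vocab(policy$namespaces)) {
  .graph(.triplify_targets_tbl(.as_row(target), policy, vocab), policy)
}

# ---- documents --------------------------------------------------------------

.triplify_documents_tbl <- function(docs, policy, vocab) {
  d <- docs[docs$doc_id != -1L, ]
  if (nrow(d) == 0) return(list())
  iri <- mint_uri("resource", paste0("r", d$doc_id), policy)
  rows <- list(triples_iri(iri, vocab$rdf_type, vocab$class_article))
  add_lit <- function(rows, col, pred, datatype = NA_character_) {
    hv <- which(!is.na(d[[col]]))
    if (length(hv) == 0) return(rows)
    c(rows, list(triples_lit(iri[hv], pred, d[[col]][hv],
                             datatype = datatype)))
  }
  rows <- add_lit(rows, "pmid", vocab$pmid)
  rows <- add_lit(rows, "doi", vocab$doi)
  rows <- add_lit(rows, "title", vocab$title)
  rows <- add_lit(rows, "journal", vocab$journal)
  rows <- add_lit(rows, "year", vocab$year, datatype = vocab$xsd_integer)
  rows
}

#' Convert a document record
#'
#' The sentinel `doc_id = -1` (the unpublished dataset) is not a valid
#' article and produces an empty graph.  Every other document becomes a
#' `bibo:Article` under the resource namespace (`r<doc_id>`), with PMID and
#' DOI identifier properties and title/journal/year when present.
#'
#' @param doc One-row data frame (or named list) of document columns.
#' @inheritParams triplify_molecule
#' @return An `rdf_graph`.
#' @export
triplify_document <- function(doc, policy = uri_policy(),
                              vocab = chembl_vocab(policy$namespaces)) {
  .graph(.triplify_documents_tbl(.as_row(doc), policy, vocab), policy)
}

# ---- whole snapshot ---------------------------------------------------------

#' Convert a whole snapshot
#'
#' Union of the per-record conversions over all seven tables, in table
#' order.  Deterministic for a fixed snapshot (blank-node labels are
#' derived from record identifiers).
#'
#' @param snapshot A validated `chembl_snapshot`.
#' @inheritParams triplify_molecule
#' @param quiet Suppress per-table progress messages.
#' @return An `rdf_graph`.
#' @export
triplify_snapshot <- function(snapshot, policy = uri_policy(),
                              vocab = chembl_vocab(policy$namespaces),
                              quiet = TRUE) {
  validate_snapshot(snapshot)
  say <- function(...) if (!quiet) message(...)
  rows <- list()
  say("molecules: ", nrow(snapshot$molecules))
  rows <- c(rows, .triplify_molecules_tbl(snapshot$molecules, policy, vocab))
  rows <- c(rows, .attach_drug_role_tbl(snapshot$molecules, policy, vocab))
  rows <- c(rows, .triplify_descriptors_tbl(snapshot$molecules,
                                            snapshot$properties,
                                            policy, vocab))
  say("assays: ", nrow(snapshot$assays))
  rows <- c(rows, .triplify_assays_tbl(snapshot$assays,
                                       snapshot$assay2target, policy, vocab))
  say("targets: ", nrow(snapshot$targets))
  rows <- c(rows, .triplify_targets_tbl(snapshot$targets, policy, vocab))
  say("activities: ", nrow(snapshot$activities))
  rows <- c(rows, .triplify_activities_tbl(snapshot$activities, policy,
                                           vocab))
  say("documents: ", nrow(snapshot$docs))
  rows <- c(rows, .triplify_documents_tbl(snapshot$docs, policy, vocab))
  .graph(rows, policy)
}
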