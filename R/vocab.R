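#' Conversion vocabulary
#'
#' Central table of every class and predicate IRI the triplifier emits.
#' Community terms (CHEMINF, ChEBI, PRO, BFO, BIBO, CiTO, SKOS, OWL) are
#' used where the semantics of the source column are clear; columns whose
#' meaning is only implied by the relational schema keep terms under the
#' legacy `chembl:` namespace.  Everything is overridable, so alternative
#' predicate spellings can be swapped in without touching the converter.
#'
#' @param namespaces Namespace table used to expand prefixes.
#' @param ... Named overrides, e.g. `citation = "<iri>"`.
#' @return Named list of IRIs with class `chembl_vocab`.
#' @export
chembl_vocab <- function(namespaces = default_namespaces(), ...) {
  ns <- function(p, local) paste0(namespaces[[p]], local)
  v <- list(
    # core classes
    class_activity        = ns("chembl", "Activity"),
    class_assay           = ns("chembl", "Assay"),
    class_target          = ns("chembl", "Target"),
    class_article         = ns("bibo", "Article"),
    class_material_entity = ns("bfo", "MaterialEntity"),
    class_chemical_entity = ns("cheminf", "CHEMINF_000000"),
    class_protein_mol     = ns("obo", "PR_000000001"),
    class_protein_target  = ns("obo", "PR_0000001"),
    class_oligosaccharide = ns("chebi", "CHEBI_50699"),
    class_oligonucleotide = ns("chebi", "CHEBI_7754"),
    class_cell            = ns("chembl", "CELL"),
    class_drug_role       = ns("chebi", "CHEBI_23888"),
    class_restriction     = ns("owl", "Restriction"),

    # rdf / rdfs / owl machinery
    rdf_type        = ns("rdf", "type"),
    subclass_of     = ns("rdfs", "subClassOf"),
    label           = ns("rdfs", "label"),
    see_also        = ns("rdfs", "seeAlso"),
    on_property     = ns("owl", "onProperty"),
    some_values     = ns("owl", "someValuesFrom"),
    equivalent_class = ns("owl", "equivalentClass"),
    same_as         = ns("owl", "sameAs"),
    exact_match     = ns("skos", "exactMatch"),
    has_role        = ns("obo", "RO_0000087"),

    # activity / assay / target description predicates (schema-implied)
    activity_type   = ns("chembl", "type"),
    standard_value  = ns("chembl", "standardValue"),
    standard_units  = ns("chembl", "standardUnits"),
    standard_relation = ns("chembl", "standardRelation"),
    on_assay        = ns("chembl", "onAssay"),
    for_molecule    = ns("chembl", "forMolecule"),
    assay_type      = ns("chembl", "assayType"),
    description     = ns("chembl", "hasDescription"),
    has_target_description = ns("chembl", "hasTargetDescription"),
    has_target      = ns("chembl", "hasTarget"),
    has_conf_score  = ns("chembl", "hasConfScore"),
    relationship_type = ns("chembl", "relationshipType"),
    multi_flag      = ns("chembl", "multiFlag"),
    complex_flag    = ns("chembl", "complexFlag"),

    # citation + bibliography
    citation        = ns("cito", "citesAsDataSource"),
    pmid            = ns("bibo", "pmid"),
    doi             = ns("bibo", "doi"),
    title           = ns("dcterms", "title"),
    journal         = ns("chembl", "journal"),
    year            = ns("chembl", "year"),

    # CHEMINF / SIO descriptor pattern
    has_attribute   = ns("cheminf", "SIO_000008"),
    has_value       = ns("cheminf", "SIO_000300"),
    calculated_by   = ns("chembl", "calculatedBy"),
    desc_smiles     = ns("cheminf", "CHEMINF_000018"),
    desc_inchi      = ns("cheminf", "CHEMINF_000113"),
    desc_inchikey   = ns("cheminf", "CHEMINF_000059"),
    desc_csid       = ns("cheminf", "CHEMINF_000405"),
    desc_alogp      = ns("cheminf", "CHEMINF_000251"),

    # datatypes
    xsd_double      = ns("xsd", "double"),
    xsd_integer     = ns("xsd", "integer"),
    xsd_boolean     = ns("xsd", "boolean")
  )
  dots <- list(...)
  v[names(dots)] <- dots
  structure(v, class = "chembl_vocab")
}

# descriptor class for a named numeric property; unmapped names get a
# term under the chembl: namespace
.property_descriptor_class <- function(property, vocab,
                                       namespaces = default_namespaces()) {
  known <- c(alogp = vocab$desc_alogp)
  out <- unname(known[property])
  miss <- is.na(out)
  out[miss] <- paste0(namespaces[["chembl"]], "descriptor_",
                      percent_encode(property[miss]))
  out
}

# chembl target-type class for the non-protein categories
.target_type_class <- function(target_type,
                               namespaces = default_namespaces()) {
  map <- c(
    ADMET = "ADMET", `CELL_LINE` = "CELL-LINE",
    `NUCLEIC_ACID` = "NUCLEIC-ACID", ORGANISM = "ORGANISM",
    SUBCELLULAR = "SUBCELLULAR", TISSUE = "TISSUE",
    UNCHECKED = "UNCHECKED", UNKNOWN = "UNKNOWN"
  )
  local <- map[target_type]
  if (any(is.na(local))) {
    stop("unknown target_type: ",
         paste(unique(target_type[is.na(local)]), collapse = ", "),
         call. = FALSE)
  }
  paste0(namespaces[["chembl"]], unname(local))
}
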