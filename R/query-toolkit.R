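#' Describe a compound-selectivity query
#'
#' Finds molecules with high affinity to protein A (activity value
#' strictly below `threshold_a`) and low affinity to protein B (value
#' strictly above `threshold_b`) for a given endpoint type, optionally
#' restricted to assay-target mappings with at least a minimum confidence
#' score (9 = direct single protein target, 0 = uncurated).  To return the
#' largest possible set, the score is ignored by default
#' (`min_confidence = NULL`).
#'
#' Targets may be given as full IRIs or as UniProt accessions (resolved
#' through the Bio2RDF link-out triples, which must then be present in the
#' queried graph).
#'
#' @param target_a,target_b Target IRI or UniProt accession.
#' @param activity_type Endpoint type string (e.g. `"IC50"`).
#' @param threshold_a High-affinity bound (strict `<`) against target A.
#' @param threshold_b Low-affinity bound (strict `>`) against target B.
#' @param units Unit string that measurements must carry verbatim; no unit
#'   conversion is attempted.
#' @param min_confidence Integer 0--9 or `NULL` to ignore the score.
#' @return A `selectivity_query` list.
#' @export
selectivity_query <- function(target_a, target_b, activity_type = "IC50",
                              threshold_a = 50, threshold_b = 200,
                              units = "nM", min_confidence = NULL) {
  stopifnot(threshold_a > 0, threshold_b > 0)
  if (!is.null(min_confidence)) {
    stopifnot(min_confidence >= 0, min_confidence <= 9)
  }
  structure(list(target_a = target_a, target_b = target_b,
                 activity_type = activity_type,
                 threshold_a = threshold_a, threshold_b = threshold_b,
                 units = units, min_confidence = min_confidence),
            class = "selectivity_query")
}

.resolve_target <- function(t, spec, vocab) {
  if (grepl("^https?://", spec)) {
    if (!spec %in% c(t$subject, t$object)) {
      stop("unknown target: ", spec, call. = FALSE)
    }
    return(spec)
  }
  # accession: find the target linked out to the Bio2RDF UniProt record
  hit <- unique(t$subject[t$object_type == "iri" &
                            grepl(paste0("uniprot:", spec, "$"), t$object)])
  if (length(hit) == 0) stop("unknown target: ", spec, call. = FALSE)
  if (length(hit) > 1) stop("ambiguous accession ", spec, ": ",
                            paste(hit, collapse = ", "), call. = FALSE)
  hit
}

# molecules with a qualifying measurement of `type` against `target_iri`
.molecules_measured <- function(t, vocab, target_iri, type, units,
                                min_confidence, keep) {
  tds <- t[t$predicate == vocab$has_target & t$object == target_iri,
           "subject", drop = TRUE]
  if (!is.null(min_confidence)) {
    sc <- t[t$predicate == vocab$has_conf_score, c("subject", "object")]
    ok_nodes <- sc$subject[suppressWarnings(as.integer(sc$object)) >=
                             min_confidence]
    tds <- intersect(tds, ok_nodes)
  }
  assays <- t[t$predicate == vocab$has_target_description &
                t$object %in% tds, "subject", drop = TRUE]
  acts <- t[t$predicate == vocab$on_assay & t$object %in% assays,
            "subject", drop = TRUE]
  ty <- t[t$predicate == vocab$activity_type & t$subject %in% acts, ]
  acts <- ty$subject[ty$object == type]
  if (length(acts) == 0) return(character(0))
  un <- t[t$predicate == vocab$standard_units & t$subject %in% acts,
          c("subject", "object")]
  mismatch <- setdiff(unique(un$object), units)
  if (length(mismatch) > 0) {
    stop("unit mismatch between query (", units, ") and data (",
         paste(mismatch, collapse = ", "),
         "); no unit conversion is performed", call. = FALSE)
  }
  acts <- intersect(acts, un$subject)
  vals <- t[t$predicate == vocab$standard_value & t$subject %in% acts,
            c("subject", "object")]
  qual <- vals$subject[keep(suppressWarnings(as.numeric(vals$object)))]
  unique(t$object[t$predicate == vocab$for_molecule &
                    t$subject %in% qual])
}

#' Find selectively binding molecules
#'
#' Molecules with at least one measurement of the queried endpoint type
#' strictly below `threshold_a` against target A *and* at least one
#' strictly above `threshold_b` against target B (existential semantics:
#' any qualifying measurement counts, mirroring the join semantics of the
#' equivalent SPARQL query).  Measurements reach targets through the
#' assay's target-confidence constructs, which is where the optional
#' confidence filter applies.  Distinct molecules are returned.
#'
#' @param graph An `rdf_graph` of a converted snapshot.
#' @param query A [selectivity_query()].
#' @param vocab A [chembl_vocab()].
#' @return Tibble with one row per selective molecule: `molecule` (IRI).
#' @export
selective_binders <- function(graph, query,
                              vocab = chembl_vocab(
                                attr(graph, "namespaces") %||%
                                  default_namespaces())) {
  stopifnot(inherits(query, "selectivity_query"))
  t <- tibble::as_tibble(graph)
  a_iri <- .resolve_target(t, query$target_a, vocab)
  b_iri <- .resolve_target(t, query$target_b, vocab)
  high <- .molecules_measured(t, vocab, a_iri, query$activity_type,
                              query$units, query$min_confidence,
                              function(v) !is.na(v) & v < query$threshold_a)
  low <- .molecules_measured(t, vocab, b_iri, query$activity_type,
                             query$units, query$min_confidence,
                             function(v) !is.na(v) & v > query$threshold_b)
  tibble::tibble(molecule = sort(intersect(high, low)))
}

#' Count resources citing a document
#'
#' Distinct resources of any kind (activities, assays, molecules, ...)
#' with a citation link to the document -- the basis of per-paper
#' citation statistics over the converted data.
#'
#' @param graph An `rdf_graph`.
#' @param doc Document resource IRI, or an integer `doc_id`.
#' @param vocab A [chembl_vocab()].
#' @param policy A [uri_policy()] (used to mint the IRI from a `doc_id`).
#' @return Integer count.
#' @export
citation_count <- function(graph, doc,
                           vocab = chembl_vocab(
                             attr(graph, "namespaces") %||%
                               default_namespaces()),
                           policy = uri_policy()) {
  if (is.numeric(doc)) {
    doc <- mint_uri("resource", paste0("r", as.integer(doc)), policy)
  }
  t <- tibble::as_tibble(graph)
  length(unique(t$subject[t$predicate == vocab$citation & t$object == doc]))
}

#' Activity-type frequency table
#'
#' Tally of the endpoint-type literals over all activities, in descending
#' order, with percentages of the activity total to one decimal.
#'
#' @param graph An `rdf_graph`.
#' @param vocab A [chembl_vocab()].
#' @return A tibble (`type`, `count`, `percentage`) with class
#'   `chembl_activity_freq`.
#' @export
activity_type_frequencies <- function(graph,
                                      vocab = chembl_vocab(
                                        attr(graph, "namespaces") %||%
                                          default_namespaces())) {
  t <- tibble::as_tibble(graph)
  ty <- t[t$predicate == vocab$activity_type, ]
  out <- ty |>
    dplyr::count(type = .data$object, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$type) |>
    dplyr::mutate(percentage = round(100 * .data$count / sum(.data$count), 1))
  structure(out, class = c("chembl_activity_freq", class(out)))
}

#' Plot activity-type frequencies
#'
#' @param object A `chembl_activity_freq` table.
#' @param top Show at most this many types.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chembl_activity_freq
#' @export
autoplot.chembl_activity_freq <- function(object, top = 10, ...) {
  d <- utils::head(tibble::as_tibble(object), top)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$type,
                                                     .data$count),
                                  y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "activities",
                  title = "Activity endpoint types") +
    ggplot2::theme_minimal()
}

# ---- SPARQL templates -------------------------------------------------------

.prefix_block <- function(ns) {
  paste0("PREFIX ", names(ns), ": <", unname(ns), ">", collapse = "\n")
}

#' SPARQL template for the selectivity query
#'
#' The same logic as [selective_binders()], rendered as SPARQL so it can
#' run against any endpoint hosting the triples.
#'
#' @param query A [selectivity_query()] whose targets are IRIs.
#' @param namespaces Namespace bindings for the PREFIX block.
#' @return Character scalar of SPARQL.
#' @export
sparql_selectivity <- function(query,
                               namespaces = default_namespaces()) {
  conf <- if (is.null(query$min_confidence)) "" else glue::glue(
    "  ?tdA chembl:hasConfScore ?csA . FILTER(?csA >= {query$min_confidence})\n",
    "  ?tdB chembl:hasConfScore ?csB . FILTER(?csB >= {query$min_confidence})\n"
  )
  glue::glue(
    '{.prefix_block(namespaces)}\n',
    'SELECT DISTINCT ?molecule WHERE {{\n',
    '  ?tdA chembl:hasTarget <{query$target_a}> .\n',
    '  ?assayA chembl:hasTargetDescription ?tdA .\n',
    '  ?actA chembl:onAssay ?assayA ;\n',
    '        chembl:type "{query$activity_type}" ;\n',
    '        chembl:standardUnits "{query$units}" ;\n',
    '        chembl:standardValue ?vA ;\n',
    '        chembl:forMolecule ?molecule .\n',
    '  FILTER(?vA < {query$threshold_a})\n',
    '  ?tdB chembl:hasTarget <{query$target_b}> .\n',
    '  ?assayB chembl:hasTargetDescription ?tdB .\n',
    '  ?actB chembl:onAssay ?assayB ;\n',
    '        chembl:type "{query$activity_type}" ;\n',
    '        chembl:standardUnits "{query$units}" ;\n',
    '        chembl:standardValue ?vB ;\n',
    '        chembl:forMolecule ?molecule .\n',
    '  FILTER(?vB > {query$threshold_b})\n',
    '{conf}}}\n'
  )
}

#' SPARQL template for citation counting
#'
#' @param doc_iri Document resource IRI.
#' @param namespaces Namespace bindings.
#' @return Character scalar of SPARQL.
#' @export
sparql_citation_count <- function(doc_iri,
                                  namespaces = default_namespaces()) {
  glue::glue(
    '{.prefix_block(namespaces)}\n',
    'SELECT (COUNT(DISTINCT ?citer) AS ?n) WHERE {{\n',
    '  ?citer cito:citesAsDataSource <{doc_iri}> .\n',
    '}}\n'
  )
}

#' SPARQL template for a class count
#'
#' @param class_kind As in [count_class()].
#' @param namespaces Namespace bindings.
#' @return Character scalar of SPARQL.
#' @export
sparql_count <- function(class_kind = c("Target", "MaterialEntity", "Assay",
                                        "Activity", "Article"),
                         namespaces = default_namespaces()) {
  class_kind <- match.arg(class_kind)
  pattern <- switch(class_kind,
    Target = "{ ?x rdfs:subClassOf chembl:Target } UNION { ?x a chembl:Target }",
    MaterialEntity = "?x rdfs:subClassOf+ bfo:MaterialEntity",
    Assay = "?x a chembl:Assay",
    Activity = "?x a chembl:Activity",
    Article = "?x a bibo:Article"
  )
  glue::glue(
    '{.prefix_block(namespaces)}\n',
    'SELECT (COUNT(DISTINCT ?x) AS ?n) WHERE {{ {pattern} }}\n'
  )
}
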