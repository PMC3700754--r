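#' Release-statistics reference counts
#'
#' The ChEMBL 13 release-note counts alongside the values the converted
#' graph is expected to yield: the assay count drops by the five untyped
#' assay rows and the document count by the sentinel unpublished entry.
#' Reference metadata for full-scale runs, not a test fixture.
#'
#' @return Tibble with columns `quantity`, `release_count`, `rdf_count`.
#' @export
chembl13_reference_counts <- function() {
  tibble::tibble(
    quantity = c("targets", "material_entities", "activities", "assays",
                 "articles"),
    release_count = c(8845L, 1143682L, 6933068L, 617681L, 44682L),
    rdf_count = c(8845L, 1143682L, 6933068L, 617676L, 44681L)
  )
}

# transitive rdfs:subClassOf closure: which subjects reach `root`
.subclass_reaches <- function(t, subclass_of, root) {
  sc <- t[t$predicate == subclass_of & t$object_type == "iri", c("subject", "object")]
  reach <- root
  repeat {
    new_nodes <- unique(sc$subject[sc$object %in% reach & !sc$subject %in% reach])
    if (length(new_nodes) == 0) break
    reach <- c(reach, new_nodes)
  }
  setdiff(reach, root)
}

#' Count entities of a class in a converted graph
#'
#' Mirrors the release-statistics count queries run against the triple
#' store: distinct subjects per class, *subclass*-based for the
#' material-entity root and for targets (class-style entities), and
#' *instance*-based (`rdf:type`) for assays, activities and articles.
#' Counting over the graph -- not over the source records -- is the point:
#' it validates the conversion itself.
#'
#' For `"MaterialEntity"` the count covers every entity whose subclass
#' chain reaches the BFO material-entity root, excluding the ontology
#' scaffolding classes themselves, i.e. all converted molecules.  For
#' `"Target"` the count is the union of subclass-style (protein) and
#' typed (all other categories) targets of the common target class.
#'
#' @param graph An `rdf_graph`.
#' @param class_kind One of `"Target"`, `"MaterialEntity"`, `"Assay"`,
#'   `"Activity"`, `"Article"`.
#' @param vocab A [chembl_vocab()].
#' @return Integer count of distinct resources.
#' @export
count_class <- function(graph,
                        class_kind = c("Target", "MaterialEntity", "Assay",
                                       "Activity", "Article"),
                        vocab = chembl_vocab(attr(graph, "namespaces") %||%
                                               default_namespaces())) {
  class_kind <- match.arg(class_kind)
  t <- tibble::as_tibble(graph)
  typed <- function(cls) {
    unique(t$subject[t$predicate == vocab$rdf_type & t$object == cls])
  }
  n <- switch(class_kind,
    Assay = length(typed(vocab$class_assay)),
    Activity = length(typed(vocab$class_activity)),
    Article = length(typed(vocab$class_article)),
    Target = {
      sub <- unique(t$subject[t$predicate == vocab$subclass_of &
                                t$object == vocab$class_target])
      length(union(sub, typed(vocab$class_target)))
    },
    MaterialEntity = {
      scaffold <- c(vocab$class_chemical_entity, vocab$class_protein_mol,
                    vocab$class_oligosaccharide, vocab$class_oligonucleotide,
                    vocab$class_cell, vocab$class_material_entity)
      reach <- .subclass_reaches(t, vocab$subclass_of,
                                 vocab$class_material_entity)
      length(setdiff(reach, scaffold))
    }
  )
  as.integer(n)
}

#' Validate a conversion against its source snapshot
#'
#' Recomputes the five class counts from the graph and compares them with
#' the source-table counts.  The conversion is correct exactly when the
#' deltas (source minus graph) have the documented structure: zero for
#' targets, material entities and activities; the number of untyped assay
#' rows for assays; and one for articles when the sentinel unpublished
#' document is present.  Any other delta is a conversion defect.
#'
#' @param snapshot The source `chembl_snapshot`.
#' @param graph The graph produced from it.
#' @param vocab A [chembl_vocab()].
#' @return A `chembl_validation` object: a tibble with one row per
#'   quantity (`source_count`, `graph_count`, `delta`, `expected_delta`,
#'   `ok`) and a `pass` attribute.
#' @export
validate_conversion <- function(snapshot, graph,
                                vocab = chembl_vocab(
                                  attr(graph, "namespaces") %||%
                                    default_namespaces())) {
  n_typeless <- sum(is.na(snapshot$assays$assay_type))
  sentinel <- sum(snapshot$docs$doc_id == -1L)
  report <- tibble::tibble(
    quantity = c("targets", "material_entities", "assays", "activities",
                 "articles"),
    source_count = c(nrow(snapshot$targets), nrow(snapshot$molecules),
                     nrow(snapshot$assays), nrow(snapshot$activities),
                     nrow(snapshot$docs)),
    graph_count = c(
      count_class(graph, "Target", vocab),
      count_class(graph, "MaterialEntity", vocab),
      count_class(graph, "Assay", vocab),
      count_class(graph, "Activity", vocab),
      count_class(graph, "Article", vocab)
    ),
    expected_delta = c(0L, 0L, n_typeless, 0L, sentinel)
  ) |>
    dplyr::mutate(delta = .data$source_count - .data$graph_count,
                  ok = .data$delta == .data$expected_delta) |>
    dplyr::relocate("delta", .before = "expected_delta")
  structure(report,
            pass = all(report$ok),
            class = c("chembl_validation", class(report)))
}

#' @export
print.chembl_validation <- function(x, ...) {
  cat("# Conversion validation:",
      if (attr(x, "pass")) "PASS" else "FAIL", "\n")
  NextMethod()
  if (!attr(x, "pass")) {
    bad <- x[!x$ok, ]
    cat("offending deltas:",
        paste(sprintf("%s (delta %d, expected %d)", bad$quantity, bad$delta,
                      bad$expected_delta), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Did a validation pass?
#' @param report A `chembl_validation`.
#' @return Logical scalar.
#' @export
validation_passed <- function(report) isTRUE(attr(report, "pass"))

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a validation report
#'
#' @param x A `chembl_validation`.
#' @param ... Unused.
#' @return A plain tibble, one row per counted quantity.
#' @method tidy chembl_validation
#' @export
tidy.chembl_validation <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a validation report
#'
#' @param x A `chembl_validation`.
#' @param ... Unused.
#' @return Tibble with `pass`, `n_quantities`, `n_mismatched`.
#' @method glance chembl_validation
#' @export
glance.chembl_validation <- function(x, ...) {
  tibble::tibble(pass = attr(x, "pass"),
                 n_quantities = nrow(x),
                 n_mismatched = sum(!x$ok))
}

#' Plot a validation report
#'
#' Observed versus expected source-minus-graph deltas per quantity;
#' matching bars mean the conversion dropped exactly what it should
#' (untyped assays, the sentinel document) and nothing else.
#'
#' @param object A `chembl_validation`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chembl_validation
#' @export
autoplot.chembl_validation <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("delta", "expected_delta"),
                        names_to = "which", values_to = "value") |>
    dplyr::mutate(which = dplyr::recode(.data$which, delta = "observed",
                                        expected_delta = "expected"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quantity, y = .data$value,
                                  fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "source count - graph count", fill = NULL,
                  title = "Conversion count deltas") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a validation report
#'
#' Human-readable text plus a machine-readable tab-separated key-value
#' table.
#'
#' @param report A `chembl_validation`.
#' @param path Path of the key-value file; the text rendering goes to
#'   `<path>.txt`.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  readr::write_tsv(tibble::as_tibble(report), path, progress = FALSE)
  txt <- c(
    paste0("conversion validation: ",
           if (attr(report, "pass")) "PASS" else "FAIL"),
    sprintf("%-18s source=%d graph=%d delta=%d expected=%d %s",
            report$quantity, report$source_count, report$graph_count,
            report$delta, report$expected_delta,
            ifelse(report$ok, "ok", "MISMATCH"))
  )
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
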