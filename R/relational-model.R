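#' @importFrom rlang %||% .data
NULL

#' Enumerations of the source schema
#'
#' Molecule types, target types and assay types recognised by the
#' converter, matching the ChEMBL 13 release vocabularies.
#'
#' @name schema-enums
#' @return Character vector of enum values.
#' @export
molecule_types <- function() {
  c("SMALL_MOLECULE", "PROTEIN", "PEPTIDE", "ANTIBODY",
    "OLIGOSACCHARIDE", "OLIGONUCLEOTIDE", "CELL")
}

#' @rdname schema-enums
#' @export
target_types <- function() {
  c("PROTEIN", "ADMET", "CELL_LINE", "NUCLEIC_ACID", "ORGANISM",
    "SUBCELLULAR", "TISSUE", "UNCHECKED", "UNKNOWN")
}

#' @rdname schema-enums
#' @export
assay_types <- function() {
  c("ADMET", "Binding", "Functional", "Physicochemical", "Unassigned")
}

# empty prototypes of the seven in-memory tables ------------------------------

.empty_tables <- function() {
  list(
    molecules = tibble::tibble(
      chembl_id = character(), pref_name = character(),
      synonyms = character(), molecule_type = character(),
      approved_drug = logical(), smiles = character(),
      inchi = character(), inchikey = character()
    ),
    properties = tibble::tibble(
      chembl_id = character(), property = character(),
      value = double(), software = character()
    ),
    assays = tibble::tibble(
      assay_id = character(), assay_type = character(),
      description = character(), doc_id = integer()
    ),
    assay2target = tibble::tibble(
      assay_id = character(), target_id = character(),
      confidence_score = integer(), relationship_type = character(),
      multi_flag = logical(), complex_flag = logical()
    ),
    targets = tibble::tibble(
      target_id = character(), target_type = character(),
      uniprot_accession = character(), label = character()
    ),
    activities = tibble::tibble(
      activity_id = character(), assay_id = character(),
      chembl_id = character(), activity_type = character(),
      std_value = double(), std_units = character(),
      relation = character(), doc_id = integer()
    ),
    docs = tibble::tibble(
      doc_id = integer(), pmid = integer(), doi = character(),
      title = character(), journal = character(), year = integer()
    )
  )
}

#' Build a relational snapshot
#'
#' Assembles the in-memory image of the source tables the converter
#' consumes and checks all invariants: unique primary keys, resolvable
#' foreign keys, confidence scores in 0--9, InChIKey only alongside an
#' InChI, and at most one sentinel document (`doc_id = -1`, the
#' "unpublished" placeholder).
#'
#' @param molecules,properties,assays,assay2target,targets,activities,docs
#'   Tibbles with the documented columns; missing tables default to empty.
#' @param check Validate invariants (default `TRUE`).
#' @return A `chembl_snapshot`: a named list of tibbles.
#' @export
chembl_snapshot <- function(molecules = NULL, properties = NULL,
                            assays = NULL, assay2target = NULL,
                            targets = NULL, activities = NULL,
                            docs = NULL, check = TRUE) {
  proto <- .empty_tables()
  fill <- function(x, name) {
    if (is.null(x) || nrow(x) == 0) return(proto[[name]])
    x <- tibble::as_tibble(x)
    miss <- setdiff(names(proto[[name]]), names(x))
    if (length(miss) > 0) {
      stop("table '", name, "' is missing columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    x <- x[names(proto[[name]])]
    for (col in names(x)) {
      target_class <- class(proto[[name]][[col]])[1]
      x[[col]] <- switch(target_class,
        character = as.character(x[[col]]),
        integer = as.integer(x[[col]]),
        numeric = as.double(x[[col]]),
        logical = if (is.numeric(x[[col]])) x[[col]] != 0 else as.logical(x[[col]])
      )
    }
    x
  }
  snapshot <- structure(
    list(
      molecules = fill(molecules, "molecules"),
      properties = fill(properties, "properties"),
      assays = fill(assays, "assays"),
      assay2target = fill(assay2target, "assay2target"),
      targets = fill(targets, "targets"),
      activities = fill(activities, "activities"),
      docs = fill(docs, "docs")
    ),
    class = "chembl_snapshot"
  )
  if (check) validate_snapshot(snapshot)
  snapshot
}

#' @export
print.chembl_snapshot <- function(x, ...) {
  cat("<chembl_snapshot>\n")
  for (nm in names(x)) cat(sprintf("  %-13s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Validate snapshot integrity
#'
#' Errors (naming the offending identifiers) on duplicate primary keys,
#' dangling foreign keys, confidence scores outside 0--9, an InChIKey
#' without an InChI, non-finite property values, or a repeated sentinel
#' document.
#'
#' @param snapshot A `chembl_snapshot`.
#' @return The snapshot, invisibly.
#' @export
validate_snapshot <- function(snapshot) {
  s <- snapshot
  dup <- function(x) unique(x[duplicated(x)])
  fail <- function(...) stop(..., call. = FALSE)

  d <- dup(s$molecules$chembl_id)
  if (length(d)) fail("duplicate chembl_id: ", paste(d, collapse = ", "))
  d <- dup(s$assays$assay_id)
  if (length(d)) fail("duplicate assay_id: ", paste(d, collapse = ", "))
  d <- dup(s$targets$target_id)
  if (length(d)) fail("duplicate target_id: ", paste(d, collapse = ", "))
  d <- dup(s$activities$activity_id)
  if (length(d)) fail("duplicate activity_id: ", paste(d, collapse = ", "))
  d <- dup(s$docs$doc_id)
  if (length(d)) fail("duplicate doc_id: ", paste(d, collapse = ", "))
  if (sum(s$docs$doc_id == -1L, na.rm = TRUE) > 1) {
    fail("sentinel doc_id -1 occurs more than once")
  }

  dangling <- function(keys, universe, from, to) {
    bad <- unique(keys[!is.na(keys) & !keys %in% universe])
    if (length(bad)) {
      fail("dangling foreign key: ", from, " references missing ", to, " ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  dangling(s$activities$assay_id, s$assays$assay_id,
           "activities.assay_id", "assay")
  dangling(s$activities$chembl_id, s$molecules$chembl_id,
           "activities.chembl_id", "molecule")
  dangling(s$activities$doc_id, s$docs$doc_id, "activities.doc_id", "doc")
  dangling(s$assays$doc_id, s$docs$doc_id, "assays.doc_id", "doc")
  dangling(s$assay2target$assay_id, s$assays$assay_id,
           "assay2target.assay_id", "assay")
  dangling(s$assay2target$target_id, s$targets$target_id,
           "assay2target.target_id", "target")
  dangling(s$properties$chembl_id, s$molecules$chembl_id,
           "compound_properties.chembl_id", "molecule")

  cs <- s$assay2target$confidence_score
  if (any(is.na(cs)) || any(cs < 0L | cs > 9L)) {
    fail("confidence_score outside 0-9 for assay_id ",
         paste(utils::head(s$assay2target$assay_id[
           is.na(cs) | cs < 0L | cs > 9L], 5), collapse = ", "))
  }
  bad_mt <- setdiff(unique(s$molecules$molecule_type), molecule_types())
  if (length(bad_mt)) fail("unknown molecule_type: ",
                           paste(bad_mt, collapse = ", "))
  bad_tt <- setdiff(unique(s$targets$target_type), target_types())
  if (length(bad_tt)) fail("unknown target_type: ",
                           paste(bad_tt, collapse = ", "))
  orphan_key <- s$molecules$chembl_id[
    !is.na(s$molecules$inchikey) & is.na(s$molecules$inchi)]
  if (length(orphan_key)) {
    fail("InChIKey without InChI for ", paste(orphan_key, collapse = ", "))
  }
  if (any(!is.finite(s$properties$value))) {
    fail("non-numeric property value for ",
         paste(s$properties$chembl_id[!is.finite(s$properties$value)],
               collapse = ", "))
  }
  invisible(snapshot)
}

# file-level layout mirrors the ChEMBL 13 table names ------------------------

.table_files <- c(
  "molecule_dictionary", "compound_structures", "compound_properties",
  "assays", "assay2target", "target_dictionary", "activities", "docs"
)

#' Write a snapshot as delimited text
#'
#' One UTF-8 tab-separated file per source table, named after the ChEMBL 13
#' tables (`molecule_dictionary`, `compound_structures`,
#' `compound_properties`, `assays`, `assay2target`, `target_dictionary`,
#' `activities`, `docs`), header row included.  Absent values are written
#' as empty fields; booleans as 0/1.
#'
#' @param snapshot A `chembl_snapshot`.
#' @param path Directory to write into (created if needed).
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  as01 <- function(x) ifelse(is.na(x), NA_integer_, as.integer(x))
  m <- snapshot$molecules
  tabs <- list(
    molecule_dictionary = tibble::tibble(
      chembl_id = m$chembl_id, pref_name = m$pref_name,
      synonyms = m$synonyms, molecule_type = m$molecule_type,
      approved_drug = as01(m$approved_drug)
    ),
    compound_structures = tibble::tibble(
      chembl_id = m$chembl_id, canonical_smiles = m$smiles,
      standard_inchi = m$inchi, standard_inchi_key = m$inchikey
    ) |> dplyr::filter(!is.na(.data$canonical_smiles) |
                         !is.na(.data$standard_inchi) |
                         !is.na(.data$standard_inchi_key)),
    compound_properties = snapshot$properties,
    assays = snapshot$assays,
    assay2target = dplyr::mutate(
      snapshot$assay2target,
      multi_flag = as01(.data$multi_flag),
      complex_flag = as01(.data$complex_flag)
    ),
    target_dictionary = snapshot$targets,
    activities = snapshot$activities,
    docs = snapshot$docs
  )
  for (nm in names(tabs)) {
    readr::write_tsv(tabs[[nm]], file.path(path, paste0(nm, ".tsv")),
                     na = "", progress = FALSE)
  }
  invisible(path)
}

.tsv_col_types <- list(
  molecule_dictionary = readr::cols(
    chembl_id = "c", pref_name = "c", synonyms = "c",
    molecule_type = "c", approved_drug = "i"
  ),
  compound_structures = readr::cols(
    chembl_id = "c", canonical_smiles = "c",
    standard_inchi = "c", standard_inchi_key = "c"
  ),
  compound_properties = readr::cols(
    chembl_id = "c", property = "c", value = "d", software = "c"
  ),
  assays = readr::cols(
    assay_id = "c", assay_type = "c", description = "c", doc_id = "i"
  ),
  assay2target = readr::cols(
    assay_id = "c", target_id = "c", confidence_score = "i",
    relationship_type = "c", multi_flag = "i", complex_flag = "i"
  ),
  target_dictionary = readr::cols(
    target_id = "c", target_type = "c", uniprot_accession = "c", label = "c"
  ),
  activities = readr::cols(
    activity_id = "c", assay_id = "c", chembl_id = "c",
    activity_type = "c", std_value = "d", std_units = "c",
    relation = "c", doc_id = "i"
  ),
  docs = readr::cols(
    doc_id = "i", pmid = "i", doi = "c", title = "c", journal = "c",
    year = "i"
  )
)

#' Load a relational snapshot
#'
#' Reads the eight source tables either from a directory of tab-separated
#' files (as written by [write_snapshot()]) or from an embedded SQLite
#' database file using the same table and column names.  Empty delimited
#' fields are read as absent (SQL `NULL` has no delimited-text
#' representation).  A missing table is fatal; so is any dangling foreign
#' key, reported with the offending identifiers.
#'
#' @param path Directory (tsv dialect) or database file (sqlite dialect).
#' @param dialect `"tsv"` or `"sqlite"`.
#' @return A validated `chembl_snapshot`.
#' @export
read_snapshot <- function(path, dialect = c("tsv", "sqlite")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    if (!dir.exists(path)) stop("no such fixture directory: ", path,
                                call. = FALSE)
    tabs <- lapply(.table_files, function(nm) {
      f <- file.path(path, paste0(nm, ".tsv"))
      if (!file.exists(f)) stop("missing table file: ", f, call. = FALSE)
      readr::read_tsv(f, col_types = .tsv_col_types[[nm]], na = "",
                      progress = FALSE)
    })
    names(tabs) <- .table_files
  } else {
    if (!requireNamespace("RSQLite", quietly = TRUE)) {
      stop("the sqlite dialect requires the RSQLite package", call. = FALSE)
    }
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    have <- DBI::dbListTables(con)
    miss <- setdiff(.table_files, have)
    if (length(miss)) stop("missing table(s) in database: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    tabs <- lapply(.table_files, function(nm) {
      tibble::as_tibble(DBI::dbReadTable(con, nm))
    })
    names(tabs) <- .table_files
  }
  md <- tabs$molecule_dictionary
  cs <- tabs$compound_structures
  molecules <- dplyr::left_join(md, cs, by = "chembl_id") |>
    dplyr::rename(smiles = "canonical_smiles", inchi = "standard_inchi",
                  inchikey = "standard_inchi_key")
  chembl_snapshot(
    molecules = molecules,
    properties = tabs$compound_properties,
    assays = tabs$assays,
    assay2target = tabs$assay2target,
    targets = tabs$target_dictionary,
    activities = tabs$activities,
    docs = tabs$docs
  )
}

#' Write a snapshot into an SQLite database file
#'
#' Companion to the `"sqlite"` dialect of [read_snapshot()].
#'
#' @param snapshot A `chembl_snapshot`.
#' @param path Database file path.
#' @return `path`, invisibly.
#' @export
write_snapshot_sqlite <- function(snapshot, path) {
  if (!requireNamespace("RSQLite", quietly = TRUE)) {
    stop("writing sqlite requires the RSQLite package", call. = FALSE)
  }
  tmp <- tempfile("snap")
  write_snapshot(snapshot, tmp)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  for (nm in .table_files) {
    DBI::dbWriteTable(
      con, nm,
      as.data.frame(readr::read_tsv(file.path(tmp, paste0(nm, ".tsv")),
                                    col_types = .tsv_col_types[[nm]],
                                    na = "", progress = FALSE)),
      overwrite = TRUE
    )
  }
  unlink(tmp, recursive = TRUE)
  invisible(path)
}
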