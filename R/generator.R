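#' Configuration for the synthetic snapshot generator
#'
#' Desk-scale defaults emulate the structure of a ChEMBL 13 style release:
#' mostly small molecules with a sprinkling of biologics and cells, assays
#' dominated by binding/functional types with a handful lacking an assay
#' type (the default fraction leaves exactly 5 of 200 assays typeless,
#' mirroring the handful of untyped assay rows in the real release), an
#' activity-type mix led by Potency and IC50, per-target confidence scores
#' over the full 0--9 range, documents with PMIDs and DOIs, and the
#' sentinel "unpublished" document `doc_id = -1`.
#'
#' @param n_molecules,n_targets,n_assays,n_activities,n_documents Table
#'   sizes (exact).
#' @param seed Integer seed; generation is a pure function of the config
#'   including this seed.
#' @param fraction_assays_missing_type Fraction of assays whose type is
#'   absent; exactly `ceiling(fraction * n_assays)` rows are left untyped.
#' @param include_sentinel_doc Include the `doc_id = -1` sentinel row.
#' @param fraction_overlong_inchi Fraction of molecules whose InChI is made
#'   longer than the default InChI-IRI length cap, so no identity link can
#'   be built for them.
#' @param fraction_approved Fraction of molecules flagged as approved drugs.
#' @param planted_selectivity Optional [plant_selectivity()] description of
#'   molecules to plant that selectively bind one target over another.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_molecules = 300L, n_targets = 40L,
                           n_assays = 200L, n_activities = 1200L,
                           n_documents = 60L, seed = 1L,
                           fraction_assays_missing_type = 0.025,
                           include_sentinel_doc = TRUE,
                           fraction_overlong_inchi = 0.02,
                           fraction_approved = 0.05,
                           planted_selectivity = NULL) {
  counts <- c(n_molecules, n_targets, n_assays, n_activities, n_documents)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  fracs <- c(fraction_assays_missing_type, fraction_overlong_inchi,
             fraction_approved)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must be in [0, 1]",
                                       call. = FALSE)
  if (!is.null(planted_selectivity)) {
    p <- planted_selectivity
    if (p$k > n_molecules) {
      stop("planted_selectivity k exceeds molecule count", call. = FALSE)
    }
    if (n_targets < 2 || n_assays < 2 + ceiling(fraction_assays_missing_type * n_assays) ||
        n_activities < 2 * p$k) {
      stop("config too small to plant selectivity: need >= 2 targets, ",
           "2 typed assays and 2*k activities", call. = FALSE)
    }
  }
  structure(list(
    n_molecules = as.integer(n_molecules), n_targets = as.integer(n_targets),
    n_assays = as.integer(n_assays), n_activities = as.integer(n_activities),
    n_documents = as.integer(n_documents), seed = as.integer(seed),
    fraction_assays_missing_type = fraction_assays_missing_type,
    include_sentinel_doc = isTRUE(include_sentinel_doc),
    fraction_overlong_inchi = fraction_overlong_inchi,
    fraction_approved = fraction_approved,
    planted_selectivity = planted_selectivity
  ), class = "fixture_config")
}

#' Describe planted selective binders
#'
#' @param target_a,target_b Target identifiers (created as protein targets
#'   with the given UniProt accessions if not otherwise generated).
#' @param k Number of molecules to plant.
#' @param activity_type Endpoint type of the planted measurements.
#' @param value_a High-affinity value measured against target A.
#' @param value_b Low-affinity value measured against target B.
#' @param units Unit string for both measurements.
#' @param accession_a,accession_b UniProt accessions for the two targets.
#' @return A named list.
#' @export
plant_selectivity <- function(target_a = "t900001", target_b = "t900002",
                              k = 7L, activity_type = "IC50",
                              value_a = 10, value_b = 1000, units = "nM",
                              accession_a = "P24941",
                              accession_b = "P11802") {
  stopifnot(k >= 0, value_a > 0, value_b > 0)
  list(target_a = target_a, target_b = target_b, k = as.integer(k),
       activity_type = activity_type, value_a = value_a, value_b = value_b,
       units = units, accession_a = accession_a, accession_b = accession_b)
}

# a syntactically InChI-shaped string (synthetic; not a real structure)
.synth_inchi <- function(n, overlong = FALSE) {
  vapply(seq_len(n), function(i) {
    nc <- sample(4:30, 1)
    nh <- sample(4:40, 1)
    core <- sprintf("InChI=1S/C%dH%d%s/c%s/h%s", nc, nh,
                    sample(c("", "N2O", "O2", "NO3", "ClN"), 1),
                    paste(sample(1:20, sample(4:9, 1), replace = TRUE),
                          collapse = "-"),
                    paste(sample(1:12, sample(2:5, 1), replace = TRUE),
                          collapse = ","))
    if (overlong) {
      core <- paste0(core, "/t", paste(sample(1:99, 1100, replace = TRUE),
                                       collapse = ","))
    }
    core
  }, character(1))
}

.synth_inchikey <- function(n) {
  blk <- function(k) {
    vapply(seq_len(n), function(i)
      paste(sample(LETTERS, k, replace = TRUE), collapse = ""), character(1))
  }
  paste0(blk(14), "-", blk(10), "-N")
}

.synth_smiles <- function(n) {
  frags <- c("C", "CC", "C(C)", "c1ccccc1", "N", "O", "CO", "C(=O)O",
             "Cl", "F", "CN", "S")
  vapply(seq_len(n), function(i) {
    paste(sample(frags, sample(2:6, 1), replace = TRUE), collapse = "")
  }, character(1))
}

.activity_type_pool <- function() {
  # leading endpoint shares as reported for the source release, remainder
  # spread over a tail of other endpoint names
  tibble::tibble(
    type = c("Potency", "IC50", "MIC", "Inhibition", "Ki",
             "EC50", "AC50", "GI50", "Activity", "Kd"),
    weight = c(0.43, 0.13, 0.046, 0.037, 0.036,
               0.09, 0.06, 0.06, 0.06, 0.051),
    units = c("nM", "nM", "ug.mL-1", "%", "nM",
              "nM", "nM", "nM", NA, "nM")
  )
}

#' Generate a synthetic relational snapshot
#'
#' Deterministic given the config (including its seed): the same config
#' yields byte-identical snapshots.  Table sizes match the config exactly.
#' When selectivity is planted, the two planted targets are served by two
#' dedicated typed binding assays used only by the planted measurements,
#' and background assay--target assignments avoid the planted targets, so
#' an exhaustive relational filter recovers exactly the `k` planted
#' molecules.
#'
#' @param config A [fixture_config()].
#' @return A validated `chembl_snapshot`.
#' @export
generate_snapshot <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, .generate_snapshot_impl(config))
}

.generate_snapshot_impl <- function(cfg) {
  p <- cfg$planted_selectivity

  # --- documents -------------------------------------------------------------
  nd <- cfg$n_documents
  n_real <- if (cfg$include_sentinel_doc) nd - 1L else nd
  if (n_real < 0) stop("n_documents must be >= 1 when the sentinel is included",
                       call. = FALSE)
  docs <- tibble::tibble(
    doc_id = seq_len(n_real),
    pmid = ifelse(stats::runif(n_real) < 0.8,
                  sample(10000000L:25000000L, n_real), NA_integer_),
    doi = ifelse(stats::runif(n_real) < 0.7,
                 sprintf("10.1016/%04d-%03dX(%02d)%05d-%d",
                         sample(1000:9999, n_real, TRUE),
                         sample(100:999, n_real, TRUE),
                         sample(90:99, n_real, TRUE),
                         sample(10000:99999, n_real, TRUE),
                         sample(0:9, n_real, TRUE)),
                 NA_character_),
    title = sprintf("Synthesis and SAR of series %d", seq_len(n_real)),
    journal = sample(c("J. Med. Chem.", "Bioorg. Med. Chem. Lett.",
                       "Eur. J. Med. Chem."), n_real, TRUE),
    year = sample(1990:2011, n_real, TRUE)
  )
  if (cfg$include_sentinel_doc) {
    docs <- dplyr::bind_rows(docs, tibble::tibble(
      doc_id = -1L, pmid = NA_integer_, doi = NA_character_,
      title = NA_character_, journal = NA_character_, year = NA_integer_
    ))
  }

  # --- targets ---------------------------------------------------------------
  nt <- cfg$n_targets
  t_types <- sample(target_types(), nt, TRUE,
                    prob = c(0.6, 0.05, 0.08, 0.03, 0.06, 0.02, 0.04,
                             0.06, 0.06))
  targets <- tibble::tibble(
    target_id = paste0("t", 100000L + seq_len(nt)),
    target_type = t_types,
    uniprot_accession = ifelse(
      t_types == "PROTEIN" & stats::runif(nt) < 0.9,
      sprintf("%s%05d", sample(c("P", "Q", "O"), nt, TRUE),
              sample(1:99999, nt)),
      NA_character_),
    label = paste("Target", seq_len(nt))
  )
  if (!is.null(p)) {
    planted_rows <- tibble::tibble(
      target_id = c(p$target_a, p$target_b),
      target_type = "PROTEIN",
      uniprot_accession = c(p$accession_a, p$accession_b),
      label = c("Cyclin-dependent kinase 2", "Cyclin-dependent kinase 4")
    )
    targets <- dplyr::bind_rows(
      planted_rows,
      dplyr::filter(targets, !.data$target_id %in% planted_rows$target_id)
    )
    targets <- targets[seq_len(nt), ]
  }

  # --- molecules -------------------------------------------------------------
  nm <- cfg$n_molecules
  m_types <- sample(molecule_types(), nm, TRUE,
                    prob = c(0.85, 0.04, 0.05, 0.02, 0.01, 0.01, 0.02))
  chembl_id <- paste0("ChEMBL", sample(100000L:999999L, nm))
  small <- m_types == "SMALL_MOLECULE"
  has_struct <- small & stats::runif(nm) < 0.95
  inchi <- rep(NA_character_, nm)
  inchi[has_struct] <- .synth_inchi(sum(has_struct))
  n_over <- ceiling(cfg$fraction_overlong_inchi * nm)
  over_idx <- utils::head(which(has_struct), n_over)
  if (length(over_idx) > 0) {
    inchi[over_idx] <- .synth_inchi(length(over_idx), overlong = TRUE)
  }
  inchikey <- rep(NA_character_, nm)
  inchikey[has_struct] <- .synth_inchikey(sum(has_struct))
  smiles <- rep(NA_character_, nm)
  smiles[has_struct] <- .synth_smiles(sum(has_struct))
  n_appr <- round(cfg$fraction_approved * nm)
  approved <- rep(FALSE, nm)
  approved[sample.int(nm, n_appr)] <- TRUE
  n_syn <- stats::rpois(nm, 0.7)
  molecules <- tibble::tibble(
    chembl_id = chembl_id,
    pref_name = ifelse(stats::runif(nm) < 0.4,
                       paste("compound", seq_len(nm)), NA_character_),
    synonyms = ifelse(n_syn == 0, NA_character_,
                      vapply(seq_len(nm), function(i) {
                        if (n_syn[i] == 0) return(NA_character_)
                        paste(sprintf("syn-%d-%d", i, seq_len(n_syn[i])),
                              collapse = "|")
                      }, character(1))),
    molecule_type = m_types,
    approved_drug = approved,
    smiles = smiles, inchi = inchi, inchikey = inchikey
  )
  properties <- tidyr::expand_grid(
    chembl_id = chembl_id[has_struct],
    property = c("alogp", "hbd", "hba")
  ) |>
    dplyr::mutate(
      value = dplyr::case_when(
        .data$property == "alogp" ~ round(stats::rnorm(dplyr::n(), 2.5, 1.5), 2),
        .data$property == "hbd" ~ as.double(sample(0:5, dplyr::n(), TRUE)),
        TRUE ~ as.double(sample(0:10, dplyr::n(), TRUE))
      ),
      software = "ACD/Labs"
    )

  # --- assays ----------------------------------------------------------------
  na_ <- cfg$n_assays
  n_typeless <- ceiling(cfg$fraction_assays_missing_type * na_)
  n_planted_assays <- if (is.null(p)) 0L else 2L
  n_bg_assays <- na_ - n_planted_assays
  if (n_typeless > n_bg_assays) {
    stop("too few background assays to hold the typeless fraction",
         call. = FALSE)
  }
  a_type <- sample(assay_types(), n_bg_assays, TRUE,
                   prob = c(0.10, 0.55, 0.30, 0.04, 0.01))
  a_type[sample.int(n_bg_assays, n_typeless)] <- NA_character_
  assays <- tibble::tibble(
    assay_id = paste0("a", seq_len(n_bg_assays)),
    assay_type = a_type,
    description = paste("Assay number", seq_len(n_bg_assays)),
    doc_id = sample(docs$doc_id, n_bg_assays, TRUE)
  )
  bg_targets <- targets$target_id
  if (!is.null(p)) bg_targets <- setdiff(bg_targets, c(p$target_a, p$target_b))
  n_map <- 1L + (stats::runif(n_bg_assays) < 0.2)
  assay2target <- tibble::tibble(
    assay_id = rep(assays$assay_id, n_map),
    target_id = sample(bg_targets, sum(n_map), TRUE),
    confidence_score = sample(0:9, sum(n_map), TRUE),
    relationship_type = sample(c("D", "H", "M", NA), sum(n_map), TRUE),
    multi_flag = stats::runif(sum(n_map)) < 0.1,
    complex_flag = stats::runif(sum(n_map)) < 0.05
  ) |> dplyr::distinct(.data$assay_id, .data$target_id, .keep_all = TRUE)

  if (!is.null(p)) {
    pa <- tibble::tibble(
      assay_id = c("aSELA", "aSELB"),
      assay_type = "Binding",
      description = c("Planted binding assay on target A",
                      "Planted binding assay on target B"),
      doc_id = sample(docs$doc_id[docs$doc_id != -1L], 2L, TRUE)
    )
    assays <- dplyr::bind_rows(assays, pa)
    assay2target <- dplyr::bind_rows(assay2target, tibble::tibble(
      assay_id = c("aSELA", "aSELB"),
      target_id = c(p$target_a, p$target_b),
      confidence_score = 9L,
      relationship_type = "D",
      multi_flag = FALSE, complex_flag = FALSE
    ))
  }

  # --- activities ------------------------------------------------------------
  nact <- cfg$n_activities
  n_planted_act <- if (is.null(p)) 0L else 2L * p$k
  n_bg <- nact - n_planted_act
  pool <- .activity_type_pool()
  ty <- sample(pool$type, n_bg, TRUE, prob = pool$weight)
  units <- pool$units[match(ty, pool$type)]
  val <- round(stats::rlnorm(n_bg, log(500), 1.5), 3)
  no_val <- stats::runif(n_bg) < 0.03
  val[no_val] <- NA_real_
  units[no_val] <- NA_character_
  rel <- sample(c("=", "<", ">"), n_bg, TRUE, prob = c(0.85, 0.08, 0.07))
  rel[no_val] <- NA_character_
  bg_assay_ids <- assays$assay_id[!assays$assay_id %in% c("aSELA", "aSELB")]
  activities <- tibble::tibble(
    activity_id = paste0("a", 300000L + seq_len(n_bg)),
    assay_id = sample(bg_assay_ids, n_bg, TRUE),
    chembl_id = sample(chembl_id, n_bg, TRUE),
    activity_type = ty,
    std_value = val, std_units = units, relation = rel,
    doc_id = sample(docs$doc_id, n_bg, TRUE)
  )
  if (!is.null(p) && p$k > 0) {
    sel_mols <- chembl_id[seq_len(p$k)]
    doc_choice <- sample(docs$doc_id[docs$doc_id != -1L], 1L)
    planted <- tibble::tibble(
      activity_id = paste0("a", 600000L + seq_len(2L * p$k)),
      assay_id = rep(c("aSELA", "aSELB"), each = p$k),
      chembl_id = rep(sel_mols, 2L),
      activity_type = p$activity_type,
      std_value = rep(c(p$value_a, p$value_b), each = p$k),
      std_units = p$units,
      relation = "=",
      doc_id = doc_choice
    )
    activities <- dplyr::bind_rows(activities, planted)
  }

  chembl_snapshot(
    molecules = molecules, properties = properties, assays = assays,
    assay2target = assay2target, targets = targets,
    activities = activities, docs = docs
  )
}

#' Identifiers of the molecules planted by a config
#'
#' @param config A [fixture_config()] with `planted_selectivity` set.
#' @param snapshot The snapshot generated from that config.
#' @return Character vector of planted `chembl_id`s.
#' @export
planted_molecule_ids <- function(config, snapshot) {
  p <- config$planted_selectivity
  if (is.null(p)) return(character(0))
  unique(snapshot$activities$chembl_id[snapshot$activities$assay_id == "aSELA"])
}
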