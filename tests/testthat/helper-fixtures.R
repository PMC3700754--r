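# Small hand-built snapshot used across tests: 3 molecules (one approved,
# one protein, one with no structure), 2 targets, 2 assays (one typeless),
# 2 docs (one sentinel), 4 activities.
tiny_snapshot <- function() {
  chembl_snapshot(
    molecules = tibble::tibble(
      chembl_id = c("ChEMBL1", "ChEMBL2", "ChEMBL3"),
      pref_name = c("aspirinoid", NA, "biologic"),
      synonyms = c("asp|acetyl-thing", NA, NA),
      molecule_type = c("SMALL_MOLECULE", "SMALL_MOLECULE", "PROTEIN"),
      approved_drug = c(TRUE, FALSE, FALSE),
      smiles = c("CC(=O)Oc1ccccc1C(=O)O", "CCO", NA),
      inchi = c("InChI=1S/C9H8O4/c1-6(10)13-8-5-3-2-4-7(8)9(11)12/h2-5H,1H3,(H,11,12)",
                "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3", NA),
      inchikey = c("BSYNRYMUTXBXSQ-UHFFFAOYSA-N", "LFQSCWFLJHTTHZ-UHFFFAOYSA-N", NA)
    ),
    properties = tibble::tibble(
      chembl_id = c("ChEMBL1", "ChEMBL1"),
      property = c("alogp", "hbd"),
      value = c(1.31, 1), software = c("ACD/Labs", NA)
    ),
    assays = tibble::tibble(
      assay_id = c("a17", "a18"),
      assay_type = c("Binding", NA),
      description = c("binding assay", "mystery assay"),
      doc_id = c(10L, 10L)
    ),
    assay2target = tibble::tibble(
      assay_id = c("a17", "a17"),
      target_id = c("t1", "t2"),
      confidence_score = c(9L, 4L),
      relationship_type = c("D", NA),
      multi_flag = c(FALSE, TRUE),
      complex_flag = c(FALSE, NA)
    ),
    targets = tibble::tibble(
      target_id = c("t1", "t2"),
      target_type = c("PROTEIN", "ORGANISM"),
      uniprot_accession = c("P24941", NA),
      label = c("CDK2", "E. coli")
    ),
    activities = tibble::tibble(
      activity_id = paste0("act", 1:4),
      assay_id = c("a17", "a17", "a18", "a17"),
      chembl_id = c("ChEMBL1", "ChEMBL2", "ChEMBL1", "ChEMBL3"),
      activity_type = c("IC50", "IC50", "Potency", "Ki"),
      std_value = c(25, 500, 1000, NA),
      std_units = c("nM", "nM", "nM", NA),
      relation = c("=", "=", "=", NA),
      doc_id = c(10L, 10L, -1L, 10L)
    ),
    docs = tibble::tibble(
      doc_id = c(10L, -1L),
      pmid = c(12345678L, NA),
      doi = c("10.1016/0960-894X(96)00111-4", NA),
      title = c("A paper", NA),
      journal = c("J. Med. Chem.", NA),
      year = c(1996L, NA)
    )
  )
}

# Exhaustive relational filter for selective binders, written against the
# source tables with plain loops -- independent of the graph machinery.
oracle_selective <- function(snap, target_a, target_b, type, thr_a, thr_b,
                             units, min_conf = NULL) {
  qualifies <- function(mol, target, keep) {
    at <- snap$assay2target
    at <- at[at$target_id == target, ]
    if (!is.null(min_conf)) at <- at[at$confidence_score >= min_conf, ]
    # only typed assays produce triples
    typed <- snap$assays$assay_id[!is.na(snap$assays$assay_type)]
    assay_ids <- intersect(at$assay_id, typed)
    for (i in seq_len(nrow(snap$activities))) {
      a <- snap$activities[i, ]
      if (a$chembl_id != mol) next
      if (!a$assay_id %in% assay_ids) next
      if (a$activity_type != type) next
      if (is.na(a$std_units) || a$std_units != units) next
      if (is.na(a$std_value)) next
      if (keep(a$std_value)) return(TRUE)
    }
    FALSE
  }
  hits <- character(0)
  for (mol in unique(snap$molecules$chembl_id)) {
    if (qualifies(mol, target_a, function(v) v < thr_a) &&
        qualifies(mol, target_b, function(v) v > thr_b)) {
      hits <- c(hits, mol)
    }
  }
  sort(hits)
}

# Independent percent-encoder used as the length oracle for InChI IRIs
# (character-by-character over UTF-8 code units, written without the
# package's encoder).
oracle_encode <- function(s, safe = "=/?,()") {
  ok <- c(letters, LETTERS, as.character(0:9), "-", ".", "_", "~",
          strsplit(safe, "")[[1]])
  bytes <- utf8ToInt(s)  # synthetic InChIs are ASCII
  paste(vapply(bytes, function(b) {
    ch <- intToUtf8(b)
    if (b < 128 && ch %in% ok) ch else sprintf("%%%02X", b)
  }, character(1)), collapse = "")
}

expect_has_triple <- function(graph, s, p, o) {
  t <- tibble::as_tibble(graph)
  expect_true(any(t$subject == s & t$predicate == p & t$object == o),
              label = paste("graph contains", s, p, o))
}
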