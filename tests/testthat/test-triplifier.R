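v <- chembl_vocab()

mol_record <- function(type = "SMALL_MOLECULE", id = "ChEMBL406142", ...) {
  defaults <- list(chembl_id = id, pref_name = NA_character_,
                   synonyms = NA_character_, molecule_type = type,
                   approved_drug = FALSE, smiles = NA_character_,
                   inchi = NA_character_, inchikey = NA_character_)
  args <- list(...)
  defaults[names(args)] <- args
  tibble::as_tibble(defaults)
}

test_that("molecules are classes under their type-specific superclass", {
  iri <- mint_uri("molecule", "ChEMBL406142")
  g <- triplify_molecule(mol_record("SMALL_MOLECULE"))
  expect_has_triple(g, iri, v$subclass_of, v$class_chemical_entity)
  g <- triplify_molecule(mol_record("OLIGONUCLEOTIDE"))
  expect_has_triple(g, iri, v$subclass_of, v$class_oligonucleotide)
  g <- triplify_molecule(mol_record("OLIGOSACCHARIDE"))
  expect_has_triple(g, iri, v$subclass_of, v$class_oligosaccharide)
  for (ty in c("PROTEIN", "PEPTIDE", "ANTIBODY")) {
    g <- triplify_molecule(mol_record(ty))
    expect_has_triple(g, iri, v$subclass_of, v$class_protein_mol)
  }
})

test_that("every molecule type has a subclass path to the material-entity root", {
  iri <- mint_uri("molecule", "ChEMBL406142")
  for (ty in molecule_types()) {
    t <- tibble::as_tibble(triplify_molecule(mol_record(ty)))
    sc <- t[t$predicate == v$subclass_of, ]
    reach <- iri
    repeat {
      step <- unique(sc$object[sc$subject %in% reach & !sc$object %in% reach])
      if (length(step) == 0) break
      reach <- c(reach, step)
    }
    expect_true(v$class_material_entity %in% reach, label = ty)
  }
})

test_that("an unknown molecule type is an error naming the value", {
  expect_error(triplify_molecule(mol_record("GASEOUS_VIBE")), "GASEOUS_VIBE")
})

test_that("names and synonyms become labels", {
  g <- triplify_molecule(mol_record(pref_name = "aspirin",
                                    synonyms = "ASA|acetylsalicylic acid"))
  t <- tibble::as_tibble(g)
  labels <- t$object[t$predicate == v$label]
  expect_setequal(labels, c("aspirin", "ASA", "acetylsalicylic acid"))
})

test_that("the drug role is attached to approved drugs only", {
  expect_equal(nrow(attach_drug_role(mol_record(approved_drug = FALSE))), 0L)
  g <- attach_drug_role(mol_record(approved_drug = TRUE))
  t <- tibble::as_tibble(g)
  expect_true(v$class_drug_role %in% t$object)
  # encoded as a has-role restriction on the molecule class
  bn <- t$object[t$predicate == v$subclass_of]
  expect_true(startsWith(bn, "_:"))
  expect_has_triple(g, bn, v$on_property, v$has_role)
  expect_has_triple(g, bn, v$some_values, v$class_drug_role)
  # approval, not molecule type, drives the rule
  gp <- attach_drug_role(mol_record("PROTEIN", approved_drug = TRUE))
  expect_true(v$class_drug_role %in% tibble::as_tibble(gp)$object)
})

test_that("descriptor nodes appear one per present identifier/property", {
  expect_equal(nrow(triplify_descriptors(mol_record())), 0L)
  g <- triplify_descriptors(mol_record(inchikey = "BSYNRYMUTXBXSQ-UHFFFAOYSA-N",
                                       inchi = "InChI=1S/CH4/h1H4"))
  t <- tibble::as_tibble(g)
  nodes <- unique(t$subject[startsWith(t$subject, "_:")])
  expect_length(nodes, 2)
  key_nodes <- t$subject[t$predicate == v$rdf_type &
                           t$object == v$desc_inchikey]
  expect_length(key_nodes, 1)
  expect_has_triple(g, key_nodes, v$has_value, "BSYNRYMUTXBXSQ-UHFFFAOYSA-N")
})

test_that("numeric properties carry value and software provenance", {
  props <- tibble::tibble(chembl_id = "ChEMBL406142", property = "alogp",
                          value = 2.5, software = "ACD/Labs")
  g <- triplify_descriptors(mol_record(), properties = props)
  t <- tibble::as_tibble(g)
  node <- t$subject[t$predicate == v$rdf_type & t$object == v$desc_alogp]
  expect_length(node, 1)
  expect_has_triple(g, node, v$has_value, "2.5")
  expect_has_triple(g, node, v$calculated_by, "ACD/Labs")
  bad <- props
  bad$value <- NA_real_
  expect_error(triplify_descriptors(mol_record(), properties = bad),
               "non-numeric")
})

test_that("descriptor node count equals the brute-force field count", {
  set.seed(7)
  for (i in 1:20) {
    fields <- list(
      smiles = if (runif(1) < 0.5) "CCO" else NA_character_,
      inchi = if (runif(1) < 0.5) "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3"
              else NA_character_
    )
    fields$inchikey <- if (!is.na(fields$inchi) && runif(1) < 0.5)
      "LFQSCWFLJHTTHZ-UHFFFAOYSA-N" else NA_character_
    n_props <- sample(0:3, 1)
    props <- if (n_props > 0) tibble::tibble(
      chembl_id = "ChEMBLX", property = paste0("p", seq_len(n_props)),
      value = runif(n_props), software = NA_character_)
    g <- triplify_descriptors(
      do.call(mol_record, c(list(id = "ChEMBLX"), fields)),
      properties = props)
    expected <- sum(!vapply(fields, is.na, logical(1))) + n_props
    t <- tibble::as_tibble(g)
    expect_equal(length(unique(t$subject[startsWith(t$subject, "_:")])),
                 expected)
  }
})

act_record <- function(...) {
  defaults <- list(activity_id = "a31863", assay_id = "a17",
                   chembl_id = "ChEMBL1", activity_type = "Potency",
                   std_value = 5500, std_units = "nM", relation = "=",
                   doc_id = 10L)
  args <- list(...)
  defaults[names(args)] <- args
  tibble::as_tibble(defaults)
}

test_that("activities expose type, standardized value, units and links", {
  g <- triplify_activity(act_record())
  iri <- mint_uri("activity", "a31863")
  t <- tibble::as_tibble(g)
  expect_has_triple(g, iri, v$rdf_type, v$class_activity)
  expect_has_triple(g, iri, v$activity_type, "Potency")
  # endpoint type and units are plain literals, no ontology terms
  ty_row <- t[t$predicate == v$activity_type, ]
  expect_true(all(ty_row$object_type == "literal" & is.na(ty_row$datatype)))
  un_row <- t[t$predicate == v$standard_units, ]
  expect_equal(un_row$object, "nM")
  expect_true(is.na(un_row$datatype))
  val_row <- t[t$predicate == v$standard_value, ]
  expect_equal(val_row$object, "5500")
  expect_equal(val_row$datatype, v$xsd_double)
  expect_has_triple(g, iri, v$on_assay, mint_uri("assay", "a17"))
  expect_has_triple(g, iri, v$for_molecule, mint_uri("molecule", "ChEMBL1"))
  expect_has_triple(g, iri, v$citation, mint_uri("resource", "r10"))
})

test_that("only one value triple is emitted per activity", {
  # the source row may carry original literature values as well; the
  # conversion exposes exactly the standardized one
  t <- tibble::as_tibble(triplify_activity(act_record()))
  expect_equal(sum(t$predicate == v$standard_value), 1L)
  numeric_literals <- t[t$object_type == "literal" & !is.na(t$datatype) &
                          t$datatype == v$xsd_double, ]
  expect_equal(nrow(numeric_literals), 1L)
})

test_that("activities referencing the sentinel document do not cite it", {
  t <- tibble::as_tibble(triplify_activity(act_record(doc_id = -1L)))
  expect_false(any(t$predicate == v$citation))
})

test_that("a typeless assay yields no triples at all", {
  assay <- tibble::tibble(assay_id = "a18", assay_type = NA_character_,
                          description = "mystery", doc_id = 10L)
  expect_equal(nrow(triplify_assay(assay)), 0L)
})

test_that("each target assignment becomes its own confidence construct", {
  snap <- tiny_snapshot()
  g <- triplify_assay(snap$assays[1, ], snap$assay2target)
  t <- tibble::as_tibble(g)
  iri <- mint_uri("assay", "a17")
  expect_has_triple(g, iri, v$rdf_type, v$class_assay)
  constructs <- t$object[t$subject == iri &
                           t$predicate == v$has_target_description]
  expect_length(constructs, 2)
  # each construct pairs exactly one target with exactly one score
  pairing <- lapply(constructs, function(bn) {
    list(target = t$object[t$subject == bn & t$predicate == v$has_target],
         score = t$object[t$subject == bn & t$predicate == v$has_conf_score])
  })
  expect_true(all(vapply(pairing, function(p)
    length(p$target) == 1 && length(p$score) == 1, logical(1))))
  got <- vapply(pairing, function(p) paste(p$target, p$score), character(1))
  expect_setequal(got, c(paste(mint_uri("target", "t1"), 9),
                         paste(mint_uri("target", "t2"), 4)))
})

test_that("an assay with no assignments still gets its own triples", {
  assay <- tibble::tibble(assay_id = "a20", assay_type = "Functional",
                          description = NA_character_, doc_id = -1L)
  t <- tibble::as_tibble(triplify_assay(assay))
  expect_true(nrow(t) > 0)
  expect_false(any(t$predicate == v$has_target_description))
})

test_that("an out-of-range confidence score is fatal", {
  snap <- tiny_snapshot()
  at <- snap$assay2target
  at$confidence_score[1] <- 12L
  expect_error(triplify_assay(snap$assays[1, ], at), "0-9")
})

test_that("targets follow the class/instance split by type", {
  prot <- tibble::tibble(target_id = "t100122", target_type = "PROTEIN",
                         uniprot_accession = "P24941", label = "CDK2")
  g <- triplify_target(prot)
  iri <- mint_uri("target", "t100122")
  expect_has_triple(g, iri, v$subclass_of, v$class_protein_target)
  expect_has_triple(g, iri, v$subclass_of, v$class_target)
  expect_false(any(tibble::as_tibble(g)$predicate == v$rdf_type &
                     tibble::as_tibble(g)$subject == iri))

  ns <- default_namespaces()
  unk <- tibble::tibble(target_id = "t9", target_type = "UNKNOWN",
                        uniprot_accession = NA, label = "who knows")
  gu <- triplify_target(unk)
  expect_has_triple(gu, mint_uri("target", "t9"), v$rdf_type,
                    paste0(ns[["chembl"]], "UNKNOWN"))
  org <- tibble::tibble(target_id = "t10", target_type = "ORGANISM",
                        uniprot_accession = NA, label = "E. coli")
  go <- triplify_target(org)
  expect_has_triple(go, mint_uri("target", "t10"), v$rdf_type,
                    paste0(ns[["chembl"]], "ORGANISM"))
  expect_has_triple(go, mint_uri("target", "t10"), v$rdf_type, v$class_target)

  bad <- tibble::tibble(target_id = "t11", target_type = "MYSTERY",
                        uniprot_accession = NA, label = "x")
  expect_error(triplify_target(bad), "MYSTERY")
})

test_that("documents become articles except the sentinel", {
  snap <- tiny_snapshot()
  expect_equal(nrow(triplify_document(snap$docs[2, ])), 0L)
  g <- triplify_document(snap$docs[1, ])
  iri <- mint_uri("resource", "r10")
  expect_has_triple(g, iri, v$rdf_type, v$class_article)
  expect_has_triple(g, iri, v$pmid, "12345678")
  expect_has_triple(g, iri, v$doi, "10.1016/0960-894X(96)00111-4")
  bare <- tibble::tibble(doc_id = 7L, pmid = NA, doi = NA, title = NA,
                         journal = NA, year = NA)
  t <- tibble::as_tibble(triplify_document(bare))
  expect_true(any(t$predicate == v$rdf_type))
  expect_false(any(t$predicate %in% c(v$pmid, v$doi)))
})

test_that("snapshot conversion applies exactly the two exclusion rules", {
  expect_equal(nrow(triplify_snapshot(chembl_snapshot())), 0L)
  snap <- tiny_snapshot()
  g <- triplify_snapshot(snap)
  expect_equal(count_class(g, "MaterialEntity"), 3L)
  expect_equal(count_class(g, "Assay"), 1L)       # one of two is typeless
  expect_equal(count_class(g, "Article"), 1L)     # sentinel dropped
  expect_equal(count_class(g, "Activity"), 4L)
  expect_equal(count_class(g, "Target"), 2L)
})

test_that("snapshot conversion is deterministic up to isomorphism", {
  snap <- generate_snapshot(fixture_config(
    n_molecules = 10, n_targets = 4, n_assays = 8, n_activities = 30,
    n_documents = 6, seed = 13))
  expect_true(graph_isomorphic(triplify_snapshot(snap),
                               triplify_snapshot(snap)))
})

test_that("every subject IRI in a converted graph was minted by the policy", {
  snap <- tiny_snapshot()
  t <- tibble::as_tibble(triplify_snapshot(snap))
  subjects <- unique(t$subject[!startsWith(t$subject, "_:")])
  bases <- c(vapply(c("activity", "assay", "molecule", "resource", "target"),
                    function(k) mint_uri(k, "x"), character(1)))
  bases <- sub("x$", "", bases)
  ontology_classes <- c(v$class_chemical_entity, v$class_protein_mol,
                        v$class_oligosaccharide, v$class_oligonucleotide,
                        v$class_cell)
  minted <- vapply(subjects, function(s) {
    any(startsWith(s, bases)) || s %in% ontology_classes
  }, logical(1))
  expect_true(all(minted))
})

test_that("class-style and instance-style entities never swap styles", {
  snap <- generate_snapshot(fixture_config(
    n_molecules = 15, n_targets = 6, n_assays = 10, n_activities = 40,
    n_documents = 6, seed = 21))
  t <- tibble::as_tibble(triplify_snapshot(snap))
  mols <- mint_uri("molecule", snap$molecules$chembl_id)
  # molecules never instantiate their chemical superclass
  expect_false(any(t$subject %in% mols & t$predicate == v$rdf_type &
                     t$object != v$class_restriction))
  insts <- c(mint_uri("assay", snap$assays$assay_id),
             mint_uri("activity", snap$activities$activity_id))
  expect_false(any(t$subject %in% insts & t$predicate == v$subclass_of))
})

test_that("no drug-role triple exists for a non-approved molecule", {
  snap <- generate_snapshot(fixture_config(
    n_molecules = 20, n_targets = 4, n_assays = 8, n_activities = 30,
    n_documents = 5, seed = 31, fraction_approved = 0.2))
  t <- tibble::as_tibble(triplify_snapshot(snap))
  role_mols <- t$subject[t$predicate == v$subclass_of &
                           startsWith(t$object, "_:role_")]
  approved <- mint_uri("molecule",
                       snap$molecules$chembl_id[snap$molecules$approved_drug])
  expect_setequal(role_mols, approved)
})
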