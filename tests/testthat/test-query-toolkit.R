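planted_graph <- function(k = 7, seed = 5) {
  cfg <- fixture_config(n_molecules = 30, n_targets = 8, n_assays = 20,
                        n_activities = 120, n_documents = 10, seed = seed,
                        planted_selectivity = plant_selectivity(k = k))
  snap <- generate_snapshot(cfg)
  list(cfg = cfg, snap = snap,
       graph = graph_union(triplify_snapshot(snap), linkout_graph(snap)))
}

test_that("planted selective binders are recovered exactly", {
  x <- planted_graph()
  q <- selectivity_query(mint_uri("target", "t900001"),
                         mint_uri("target", "t900002"))
  hits <- selective_binders(x$graph, q)
  expect_equal(nrow(hits), 7L)
  expect_setequal(hits$molecule,
                  mint_uri("molecule", planted_molecule_ids(x$cfg, x$snap)))
})

test_that("targets can be addressed by UniProt accession via link-outs", {
  x <- planted_graph()
  q <- selectivity_query("P24941", "P11802")
  hits <- selective_binders(x$graph, q)
  expect_equal(nrow(hits), 7L)
  expect_error(
    selective_binders(x$graph, selectivity_query("P00000", "P11802")),
    "unknown target")
})

test_that("both measurements are required and inequalities are strict", {
  v <- chembl_vocab()
  snap <- tiny_snapshot()
  # build a two-target fixture by hand: m1 selective, m2 only measured on A,
  # m3 exactly at both thresholds
  snap$targets <- tibble::tibble(
    target_id = c("tA", "tB"), target_type = "PROTEIN",
    uniprot_accession = c("P1", "P2"), label = c("A", "B"))
  snap$assays <- tibble::tibble(
    assay_id = c("aa", "ab"), assay_type = "Binding",
    description = NA_character_, doc_id = 10L)
  snap$assay2target <- tibble::tibble(
    assay_id = c("aa", "ab"), target_id = c("tA", "tB"),
    confidence_score = c(9L, 3L), relationship_type = NA_character_,
    multi_flag = FALSE, complex_flag = FALSE)
  snap$activities <- tibble::tibble(
    activity_id = paste0("q", 1:5),
    assay_id = c("aa", "ab", "aa", "aa", "ab"),
    chembl_id = c("ChEMBL1", "ChEMBL1", "ChEMBL2", "ChEMBL3", "ChEMBL3"),
    activity_type = "IC50",
    std_value = c(10, 1000, 10, 50, 200),
    std_units = "nM", relation = "=", doc_id = 10L)
  g <- triplify_snapshot(snap)
  q <- selectivity_query(mint_uri("target", "tA"), mint_uri("target", "tB"),
                         threshold_a = 50, threshold_b = 200)
  hits <- selective_binders(g, q)
  expect_equal(hits$molecule, mint_uri("molecule", "ChEMBL1"))

  # confidence filter: B-side mapping has score 3, so raising the floor
  # above it empties the result
  q9 <- selectivity_query(mint_uri("target", "tA"), mint_uri("target", "tB"),
                          min_confidence = 5)
  expect_equal(nrow(selective_binders(g, q9)), 0L)

  # equal thresholds with a molecule exactly at the boundary: excluded
  qeq <- selectivity_query(mint_uri("target", "tA"), mint_uri("target", "tB"),
                           threshold_a = 50, threshold_b = 50)
  expect_false(mint_uri("molecule", "ChEMBL3") %in%
                 selective_binders(g, qeq)$molecule)
})

test_that("unit mismatches raise an error instead of silently filtering", {
  x <- planted_graph()
  q <- selectivity_query(mint_uri("target", "t900001"),
                         mint_uri("target", "t900002"), units = "ug.mL-1")
  expect_error(selective_binders(x$graph, q), "unit mismatch")
})

test_that("selective_binders equals the exhaustive relational filter", {
  for (seed in 1:5) {
    x <- planted_graph(k = (seed * 3) %% 9, seed = seed)
    p <- x$cfg$planted_selectivity
    q <- selectivity_query(mint_uri("target", p$target_a),
                           mint_uri("target", p$target_b),
                           activity_type = p$activity_type)
    expect_setequal(
      selective_binders(x$graph, q)$molecule,
      mint_uri("molecule",
               oracle_selective(x$snap, p$target_a, p$target_b,
                                p$activity_type, 50, 200, p$units)))
  }
})

test_that("raising min_confidence never enlarges the result", {
  x <- planted_graph(seed = 8)
  q0 <- selectivity_query(mint_uri("target", "t900001"),
                          mint_uri("target", "t900002"))
  prev <- selective_binders(x$graph, q0)$molecule
  for (mc in c(0, 3, 6, 9)) {
    qc <- selectivity_query(mint_uri("target", "t900001"),
                            mint_uri("target", "t900002"),
                            min_confidence = mc)
    cur <- selective_binders(x$graph, qc)$molecule
    expect_true(all(cur %in% prev), label = paste("min_confidence", mc))
    prev <- cur
  }
})

test_that("citation counts cover citers of every kind, independently per doc", {
  snap <- tiny_snapshot()
  g <- triplify_snapshot(snap)
  # doc 10 is cited by activities act1, act2, act4 and assay a17
  expect_equal(citation_count(g, 10L), 4L)
  expect_equal(citation_count(g, mint_uri("resource", "r10")), 4L)
  expect_equal(citation_count(g, 99L), 0L)

  # two docs with disjoint citers: counts independent and additive
  snap2 <- snap
  snap2$docs <- dplyr::bind_rows(
    snap2$docs, tibble::tibble(doc_id = 20L, pmid = NA_integer_,
                               doi = NA_character_, title = NA_character_,
                               journal = NA_character_, year = NA_integer_))
  snap2$activities$doc_id <- c(10L, 10L, 20L, 20L)
  g2 <- triplify_snapshot(snap2)
  n10 <- citation_count(g2, 10L)
  n20 <- citation_count(g2, 20L)
  v <- chembl_vocab()
  total <- length(unique(
    tibble::as_tibble(g2)$subject[tibble::as_tibble(g2)$predicate ==
                                    v$citation]))
  expect_equal(n10 + n20, total)
})

test_that("citation totals dominate the count of published activities", {
  snap <- generate_snapshot(fixture_config(
    n_molecules = 15, n_targets = 5, n_assays = 12, n_activities = 60,
    n_documents = 8, seed = 14))
  g <- triplify_snapshot(snap)
  total <- sum(vapply(snap$docs$doc_id[snap$docs$doc_id != -1L],
                      function(d) citation_count(g, d), integer(1)))
  # every activity except those attributed to the unpublished sentinel
  # cites its document
  expect_gte(total, sum(snap$activities$doc_id != -1L))
})

test_that("activity-type frequencies tally, order and normalize correctly", {
  snap <- tiny_snapshot()
  snap$activities <- tibble::tibble(
    activity_id = paste0("f", 1:100),
    assay_id = "a17",
    chembl_id = "ChEMBL1",
    activity_type = rep(c("Potency", "IC50", "Ki"), c(50, 30, 20)),
    std_value = 1, std_units = "nM", relation = "=", doc_id = 10L)
  g <- triplify_snapshot(snap)
  freq <- activity_type_frequencies(g)
  expect_equal(freq$type, c("Potency", "IC50", "Ki"))
  expect_equal(freq$count, c(50L, 30L, 20L))
  expect_equal(freq$percentage, c(50.0, 30.0, 20.0))
  expect_equal(sum(freq$percentage), 100, tolerance = 0.2)
  expect_equal(nrow(activity_type_frequencies(rdf_graph())), 0L)
  p <- ggplot2::autoplot(freq)
  expect_s3_class(p, "ggplot")
})

test_that("SPARQL templates carry the query parameters", {
  q <- selectivity_query("http://t/A", "http://t/B", activity_type = "Ki",
                         threshold_a = 30, threshold_b = 300,
                         min_confidence = 7)
  s <- sparql_selectivity(q)
  expect_match(s, "SELECT DISTINCT \\?molecule")
  expect_match(s, "<http://t/A>", fixed = TRUE)
  expect_match(s, "\"Ki\"", fixed = TRUE)
  expect_match(s, "\\?vA < 30")
  expect_match(s, "\\?vB > 300")
  expect_match(s, ">= 7")
  expect_match(sparql_citation_count("http://d/1"),
               "COUNT\\(DISTINCT \\?citer\\)")
  expect_match(sparql_count("Assay"), "a chembl:Assay", fixed = TRUE)
  expect_match(sparql_count("MaterialEntity"), "bfo:MaterialEntity",
               fixed = TRUE)
})
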