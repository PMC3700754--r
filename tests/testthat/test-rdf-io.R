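nasty_graph <- function() {
  rdf_graph(tibble::tibble(
    subject = c(rep(mint_uri("molecule", "X1"), 3), "_:b1", "_:b1"),
    predicate = c(rep(chembl_vocab()$label, 2), chembl_vocab()$has_attribute,
                  chembl_vocab()$has_value, chembl_vocab()$rdf_type),
    object = c("say \"hi\"", "tabs\tand\nnewlines \\ backslash", "_:b1",
               "µg/mL α→β", chembl_vocab()$desc_inchi),
    object_type = c("literal", "literal", "blank", "literal", "iri"),
    datatype = NA_character_,
    lang = c(NA, "en", NA, NA, NA)
  ))
}

test_that("Turtle and N-Triples round-trip awkward literals and blank nodes", {
  g <- nasty_graph()
  for (fmt in c("turtle", "ntriples")) {
    doc <- serialize_rdf(g, fmt)
    back <- parse_rdf(doc, fmt)
    expect_true(graph_isomorphic(g, back), label = fmt)
    lits <- tibble::as_tibble(back)
    expect_true("say \"hi\"" %in% lits$object, label = fmt)
    expect_true("µg/mL α→β" %in% lits$object, label = fmt)
  }
})

test_that("a full converted fixture round-trips isomorphically", {
  snap <- generate_snapshot(fixture_config(
    n_molecules = 15, n_targets = 5, n_assays = 10, n_activities = 40,
    n_documents = 6, seed = 19))
  g <- graph_union(triplify_snapshot(snap), linkout_graph(snap))
  expect_true(graph_isomorphic(g, parse_turtle(serialize_turtle(g))))
  expect_true(graph_isomorphic(g, parse_ntriples(serialize_ntriples(g))))
})

test_that("serialization is loss-free on counts and literal values", {
  snap <- tiny_snapshot()
  g <- triplify_snapshot(snap)
  back <- parse_ntriples(serialize_ntriples(g))
  expect_equal(nrow(back), nrow(g))
  lit <- sort(tibble::as_tibble(g)$object[
    tibble::as_tibble(g)$object_type == "literal"])
  lit2 <- sort(tibble::as_tibble(back)$object[
    tibble::as_tibble(back)$object_type == "literal"])
  expect_equal(lit2, lit)
})

test_that("an external RDF library agrees with the round trip", {
  # rdflib (via the system python) is the independent reference: it must
  # parse our Turtle and N-Triples output into graphs it itself considers
  # isomorphic, with the same triple count we serialized
  python <- Sys.which("python")
  g <- graph_union(triplify_snapshot(tiny_snapshot()), nasty_graph())
  ttl <- withr::local_tempfile(fileext = ".ttl")
  nt <- withr::local_tempfile(fileext = ".nt")
  write_rdf(g, ttl)
  write_rdf(g, nt)
  script <- paste0(
    "import rdflib, rdflib.compare\n",
    "g1 = rdflib.Graph(); g1.parse('", ttl, "', format='turtle')\n",
    "g2 = rdflib.Graph(); g2.parse('", nt, "', format='nt')\n",
    "print(len(g1), len(g2), rdflib.compare.isomorphic(g1, g2))\n")
  out <- system2(python, "-", input = script, stdout = TRUE, stderr = TRUE)
  expect_equal(utils::tail(out, 1), paste(nrow(g), nrow(g), "True"))
})

test_that("duplicate statements collapse to one (set semantics)", {
  doc <- paste0(
    "<http://x/s> <http://x/p> \"v\" .\n",
    "<http://x/s> <http://x/p> \"v\" .\n")
  expect_equal(nrow(parse_ntriples(doc)), 1L)
  ttl <- "@prefix ex: <http://x/> .\nex:s ex:p \"v\" , \"v\" ."
  expect_equal(nrow(parse_turtle(ttl)), 1L)
})

test_that("empty graphs serialize to valid empty documents", {
  g <- rdf_graph()
  expect_equal(nrow(parse_ntriples(serialize_ntriples(g))), 0L)
  expect_equal(nrow(parse_turtle(serialize_turtle(g))), 0L)
})

.row_in <- function(g, full) {
  key <- function(x) do.call(paste, c(tibble::as_tibble(x), sep = "\x1f"))
  key(g) %in% key(full)
}

test_that("truncated documents fail with a position", {
  g <- triplify_snapshot(tiny_snapshot())
  nt <- serialize_ntriples(g)
  expect_error(parse_ntriples(substr(nt, 1, nchar(nt) - 5)), "line")
  ttl <- serialize_turtle(g)
  expect_error(parse_turtle(substr(ttl, 1, nchar(ttl) - 4)), "line")
  # fuzz: truncation at random offsets either errors or yields a strict
  # subset of the statements -- never garbage triples
  set.seed(1)
  full <- parse_ntriples(nt)
  for (off in sample(nchar(nt) - 1, 8)) {
    res <- tryCatch(parse_ntriples(substr(nt, 1, off)), error = identity)
    if (!inherits(res, "error")) {
      expect_lte(nrow(res), nrow(full))
      expect_true(all(.row_in(res, full)))
    }
  }
})

test_that("bounded descriptions expand through blank-node constructs", {
  snap <- tiny_snapshot()
  g <- triplify_snapshot(snap)
  v <- chembl_vocab()
  d <- describe_resource(g, mint_uri("assay", "a17"))
  t <- tibble::as_tibble(d)
  expect_true(any(t$predicate == v$has_target &
                    t$object == mint_uri("target", "t1")))
  expect_true(any(t$predicate == v$has_conf_score & t$object == "9"))
  expect_equal(nrow(describe_resource(g, "http://example.org/unknown")), 0L)
})

test_that("molecule descriptions carry classes, labels, descriptors, links", {
  snap <- tiny_snapshot()
  g <- graph_union(triplify_snapshot(snap), linkout_graph(snap))
  v <- chembl_vocab()
  d <- tibble::as_tibble(describe_resource(g, mint_uri("molecule", "ChEMBL1")))
  expect_true(any(d$predicate == v$subclass_of &
                    d$object == v$class_chemical_entity))
  expect_true(any(d$predicate == v$label))
  expect_true(any(d$predicate == v$has_value))       # descriptor node pulled in
  expect_true(any(d$predicate == v$equivalent_class)) # OpenMolecules link
})

test_that("every minted resource has a non-empty description", {
  snap <- generate_snapshot(fixture_config(
    n_molecules = 10, n_targets = 4, n_assays = 8, n_activities = 25,
    n_documents = 5, seed = 23))
  g <- triplify_snapshot(snap)
  iris <- c(
    mint_uri("molecule", snap$molecules$chembl_id),
    mint_uri("assay",
             snap$assays$assay_id[!is.na(snap$assays$assay_type)]),
    mint_uri("activity", snap$activities$activity_id),
    mint_uri("target", snap$targets$target_id),
    mint_uri("resource",
             paste0("r", snap$docs$doc_id[snap$docs$doc_id != -1L]))
  )
  for (iri in iris) expect_gt(nrow(describe_resource(g, iri)), 0)
  expect_equal(nrow(describe_resource(g, mint_uri("assay", "zzz"))), 0L)
})

test_that("content negotiation picks RDF for RDF media types, HTML otherwise", {
  expect_equal(negotiate("text/turtle"), "turtle")
  expect_equal(negotiate("application/n-triples"), "ntriples")
  expect_equal(negotiate("text/html"), "html")
  expect_equal(negotiate("application/json"), "html")
  expect_equal(negotiate(NULL), "html")
  expect_equal(negotiate("text/html;q=0.9, text/turtle"), "html")
  expect_equal(negotiate("application/x-turtle;q=0.5"), "turtle")
})

test_that("the request handler serves descriptions with negotiation and 404s", {
  g <- triplify_snapshot(tiny_snapshot())
  uri <- mint_uri("activity", "act1")
  r <- handle_request(g, uri, "text/turtle")
  expect_equal(r$status, 200L)
  expect_equal(r$content_type, "text/turtle")
  expect_true(graph_isomorphic(parse_turtle(r$body),
                               describe_resource(g, uri)))
  rh <- handle_request(g, uri, NULL)
  expect_equal(rh$content_type, "text/html")
  expect_match(rh$body, "<table", fixed = TRUE)
  r404 <- handle_request(g, "http://linkedchemistry.info/chembl/activity/nope")
  expect_equal(r404$status, 404L)
})
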