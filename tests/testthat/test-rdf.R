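test_that("to_triples emits one triple per annotation plus the identifier", {
  approved <- c(ann_key(paste0(BAO, "BAO_0000205"), paste0(BAO, "BAO_0000219")),
                ann_key(paste0(BAO, "BAO_0000196"), paste0(BAO, "BAO_0000091")))
  g <- to_triples(761, approved,
                  free_text = data.frame(property_uri = paste0(BAO, "BAO_0002853"),
                                         text = "novel pathway"))
  expect_equal(nrow(g), 4L)
  doc_uri <- paste0(CDD, "aid761")
  expect_true(all(g$subject == doc_uri))
  aid <- g[g$predicate == paste0(CDD, "PubChemAID"), ]
  expect_equal(aid$object, "761")
  expect_equal(aid$object_type, "integer")
  lit <- g[g$object_type == "string", ]
  expect_equal(lit$object, "novel pathway")
  # empty approved set: only the identifier triple
  g0 <- to_triples(99)
  expect_equal(nrow(g0), 1L)
  expect_equal(g0$predicate, paste0(CDD, "PubChemAID"))
})

test_that("turtle serialization round-trips to an identical triple set", {
  g <- rdf_bind(
    to_triples(761, c(ann_key(paste0(BAO, "P1"), paste0(BAO, "V1")),
                      ann_key(paste0(BAO, "P2"), paste0(BAO, "V2")),
                      ann_key(paste0(BAO, "P3"), paste0(BAO, "V3")))),
    label_triples(c(setNames("has assay kit", paste0(BAO, "P1")),
                    setNames("label with \"quotes\" and\ttabs", paste0(BAO, "V1")))))
  f <- withr::local_tempfile(fileext = ".ttl")
  write_turtle(g, f)
  back <- read_turtle(f)
  expect_true(rdf_equal(g, back))
  # and the round-tripped graph re-serializes byte-identically
  f2 <- withr::local_tempfile(fileext = ".ttl")
  write_turtle(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("session decisions export to triples that survive a round trip", {
  world <- small_world(31)
  cms <- initial_calibrations(world$ms, world$features)
  s <- new_session(world$corpus$documents[[1]]$text, cms)
  top <- propose(s, 3L)
  for (k in top$key) s <- approve(s, k)
  s <- add_free_text(s, paste0(BAO, "PX"), "free text value")
  g <- session_triples(s, doc_id = 1234)
  f <- withr::local_tempfile(fileext = ".ttl")
  write_turtle(g, f)
  expect_true(rdf_equal(g, read_turtle(f)))
  expect_equal(sum(g$object_type == "uri"), 3L)
})


test_that("the assay-kit label-join query returns exactly the kit-bearing AIDs", {
  g <- synthetic_graph()
  pats <- list(c("?kit", paste0(RDFS, "label"), "HTRF cAMP Detection Kit"),
               c("?has", paste0(RDFS, "label"), "has assay kit"),
               c("?doc", "?has", "?kit"),
               c("?doc", paste0(CDD, "PubChemAID"), "?aid"))
  res <- query_triples(g, pats, select = "aid")
  expect_equal(sort(as.integer(res$aid)), c(933, 940, 1080))
})

test_that("the three-constraint instrument query returns label/AID pairs in order", {
  g <- synthetic_graph()
  pats <- list(c("?doc", paste0(BAO, "BAO_0002855"), paste0(BAO, "BAO_0000110")),
               c("?doc", paste0(BAO, "BAO_0000196"), paste0(BAO, "BAO_0000091")),
               c("?doc", paste0(BAO, "BAO_0000207"), paste0(BAO, "BAO_0000363")),
               c("?doc", paste0(BAO, "BAO_0002865"), "?q"),
               c("?q", paste0(RDFS, "label"), "?instrument"),
               c("?doc", paste0(CDD, "PubChemAID"), "?aid"))
  res <- query_triples(g, pats, select = c("instrument", "aid"))
  expect_equal(res$instrument, c("EnVision Multilabel Reader", "PHERAstar Plus"))
  expect_equal(as.integer(res$aid), c(622, 1986))
})

test_that("query is monotone and ground patterns act as membership tests", {
  g <- synthetic_graph()
  pats <- list(c("?doc", paste0(CDD, "PubChemAID"), "?aid"))
  before <- query_triples(g, pats, "aid")
  bigger <- rdf_bind(g, to_triples(555))
  after <- query_triples(bigger, pats, "aid")
  expect_true(all(before$aid %in% after$aid))
  # fully ground pattern: non-empty iff the triple is present
  hit <- list(c(paste0(CDD, "aid933"), paste0(CDD, "PubChemAID"), "933"),
              c("?doc", paste0(CDD, "PubChemAID"), "?aid"))
  expect_gt(nrow(query_triples(g, hit, "aid")), 0L)
  miss <- list(c(paste0(CDD, "aid999"), paste0(CDD, "PubChemAID"), "999"),
               c("?doc", paste0(CDD, "PubChemAID"), "?aid"))
  expect_equal(nrow(query_triples(g, miss, "aid")), 0L)
})

test_that("query rejects unbound select variables and empty graphs yield no rows", {
  g <- rdf_graph()
  pats <- list(c("?s", "?p", "?o"))
  expect_equal(nrow(query_triples(synthetic_graph(), pats, "o")),
               nrow(unique(synthetic_graph()[c("object")])))
  expect_equal(nrow(query_triples(g, list(c("?s", paste0(CDD, "PubChemAID"), "?aid")),
                                  "aid")), 0L)
  expect_error(query_triples(synthetic_graph(), pats, "nope"), "not bound")
})

test_that("pattern files parse prefixes, variables, URIs and literals", {
  f <- withr::local_tempfile(fileext = ".rq")
  writeLines(c(
    "# find kit users",
    "@prefix ex: <http://example.org/> .",
    "?kit rdfs:label \"HTRF cAMP Detection Kit\"",
    "?doc ex:uses ?kit",
    "?doc cdd:PubChemAID ?aid"), f)
  pats <- read_patterns(f)
  expect_length(pats, 3L)
  expect_equal(pats[[1]][[2]], paste0(RDFS, "label"))
  expect_equal(pats[[1]][[3]], "HTRF cAMP Detection Kit")
  expect_equal(pats[[2]][[2]], "http://example.org/uses")
  expect_equal(pats[[3]][[1]], "?doc")
})
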