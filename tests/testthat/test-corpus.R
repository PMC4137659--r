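test_that("annotation keys are built from the URI pair and split back", {
  k <- ann_key("http://x#p", "http://x#v")
  u <- ann_unkey(k)
  expect_equal(u$property_uri, "http://x#p")
  expect_equal(u$value_uri, "http://x#v")
  expect_error(ann_key("", "http://x#v"))
})

test_that("deduplication keeps the smallest doc_id per annotation-set group", {
  A <- tkey("p1", "a"); B <- tkey("p1", "b")
  corp <- make_corpus(setNames(list(c(A, B), c(A, B), A), c(5, 2, 9)))
  out <- deduplicate(corp)
  expect_equal(out$removed_count, 1L)
  ids <- vapply(out$corpus$documents, `[[`, integer(1), "doc_id")
  expect_setequal(ids, c(2L, 9L))     # doc 5 dropped, doc 2 survives its group
  # idempotent
  again <- deduplicate(out$corpus)
  expect_equal(again$removed_count, 0L)
  expect_equal(again$corpus, out$corpus)
})

test_that("deduplication of all-distinct corpora removes nothing", {
  corp <- random_toy(1)$corpus
  sig <- vapply(corp$documents, function(d) paste(d$annotations, collapse = ";"), "")
  corp2 <- new_corpus(corp$documents[!duplicated(sig)])
  expect_equal(deduplicate(corp2)$removed_count, 0L)
})

test_that("partition satisfies all its post-conditions", {
  for (seed in 1:3) {
    world <- random_toy(seed, n_docs = 30L, n_anns = 8L)
    corp <- deduplicate(world$corpus)$corpus
    parts <- partition_corpus(corp, min_train_instances = 2L)
    train_ids <- vapply(parts$train$documents, `[[`, integer(1), "doc_id")
    test_ids <- vapply(parts$test$documents, `[[`, integer(1), "doc_id")
    all_ids <- vapply(corp$documents, `[[`, integer(1), "doc_id")
    # conservation and disjointness
    expect_setequal(c(train_ids, test_ids), all_ids)
    expect_length(intersect(train_ids, test_ids), 0L)
    # every test annotation retains >= 2 training occurrences
    train_anns <- unlist(lapply(parts$train$documents, `[[`, "annotations"))
    for (d in parts$test$documents)
      for (a in d$annotations)
        expect_gte(sum(train_anns == a), 2L)
    # each annotation occurs in at most one test document
    test_ann_list <- lapply(parts$test$documents, `[[`, "annotations")
    expect_false(anyDuplicated(unlist(test_ann_list)) > 0)
  }
})

test_that("partition yields an empty test set when nothing can be spared", {
  A <- tkey("p", "a"); B <- tkey("p", "b")
  corp <- make_corpus(list(c(A), c(A), c(B), c(B)))  # every count == 2
  parts <- partition_corpus(corp, min_train_instances = 2L)
  expect_equal(n_documents(parts$test), 0L)
  expect_equal(n_documents(parts$train), 4L)
})

test_that("annotation frequency is the document fraction", {
  A <- tkey("p", "a"); B <- tkey("p", "b")
  corp <- make_corpus(list(c(A, B), c(A), c(B), c(B)))
  expect_equal(annotation_frequency(corp, A), 0.5)
  expect_equal(annotation_frequency(corp, tkey("p", "zz")), 0)
  expect_equal(annotation_frequency(corp, B), 0.75)
  expect_error(annotation_frequency(make_corpus(list()), A), "empty")
  # frequency * n is always an integer count
  for (a in c(A, B))
    expect_equal(annotation_frequency(corp, a) * 4, round(annotation_frequency(corp, a) * 4))
})

test_that("the ttl dialect drops string-literal annotation values", {
  ttl <- c(
    "@prefix bao: <http://www.bioassayontology.org/bao#> .",
    "@prefix cdd: <http://www.collaborativedrug.com/bao/curation.owl#> .",
    "cdd:aid42 cdd:PubChemAID 42 ;",
    "    bao:BAO_0000205 bao:BAO_0000219 ;",
    "    bao:BAO_0000196 bao:BAO_0000091 ;",
    "    bao:BAO_0002853 \"a free text note\" ;",
    "    cdd:hasDescription \"An assay description.\" .")
  f <- withr::local_tempfile(fileext = ".ttl")
  writeLines(ttl, f)
  corp <- load_corpus(f, "ttl")
  expect_equal(n_documents(corp), 1L)
  d <- corp$documents[[1]]
  expect_equal(d$doc_id, 42L)
  expect_equal(d$text, "An assay description.")
  expect_length(d$annotations, 2L)   # the literal-valued triple is excluded
})

test_that("an empty corpus file loads as an empty corpus", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  corp <- load_corpus(f, "simple")
  expect_equal(n_documents(corp), 0L)
  expect_equal(nrow(corp$annotations), 0L)
})

test_that("malformed simple-dialect records are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\thttp://x#p\thttp://x#v",
               "2\tnot a uri\thttp://x#v",
               "oops"), f)
  expect_warning(corp <- load_corpus(f, "simple"), "skipped")
  expect_equal(n_documents(corp), 1L)
  expect_equal(attr(corp, "skipped"), 2L)
})

test_that("corpora round-trip through both fixture dialects", {
  cfg <- generator_config(n_documents = 8L, n_properties = 4L,
                          values_per_property = 3L,
                          annotations_per_doc = c(2L, 4L),
                          background_phrases = 5L, seed = 3L)
  corp <- generate_corpus(cfg)$corpus
  for (fmt in c("simple", "ttl")) {
    path <- if (fmt == "simple") withr::local_tempdir()
            else withr::local_tempfile(fileext = ".ttl")
    write_corpus(corp, path, fmt)
    back <- read_corpus_fixture(path, fmt)
    expect_equal(n_documents(back), n_documents(corp))
    for (i in seq_along(corp$documents)) {
      expect_equal(back$documents[[i]]$doc_id, corp$documents[[i]]$doc_id)
      expect_equal(back$documents[[i]]$annotations, corp$documents[[i]]$annotations)
      expect_equal(back$documents[[i]]$text, corp$documents[[i]]$text)
    }
    expect_equal(back$annotations, corp$annotations)
  }
})

test_that("label tables load and attach labels to the universe", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("http://x#p\tassay format", "http://x#v\tbiochemical"), f)
  labels <- read_label_table(f)
  expect_equal(unname(labels["http://x#p"]), "assay format")
  corp <- make_corpus(list(tkey2 <- ann_key("http://x#p", "http://x#v")),
                      labels = labels)
  expect_equal(corp$annotations$property_label, "assay format")
  expect_equal(corp$annotations$value_label, "biochemical")
})
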