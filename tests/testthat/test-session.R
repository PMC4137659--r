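session_world <- function(seed = 51) {
  world <- small_world(seed)
  cms <- initial_calibrations(world$ms, world$features,
                              scores = loo_scores(world$ms, world$corpus,
                                                  world$features))
  corr <- build_correlation_models(world$corpus)
  cc <- calibrate_correlation(corr, world$corpus)
  c(world, list(cms = cms, corr = corr, cc = cc))
}

test_that("proposals exclude decided annotations and re-rank after decisions", {
  w <- session_world()
  s <- new_session(w$corpus$documents[[1]]$text, w$cms, w$corr, w$cc)
  p0 <- propose(s)
  expect_true(all(diff(p0$score) <= 0))          # ranked highest first
  expect_true(all(p0$has_model))
  top <- p0$key[[1]]
  s <- approve(s, top)
  expect_false(top %in% propose(s)$key)
  nxt <- propose(s)$key[[1]]
  s <- reject(s, nxt)
  expect_false(nxt %in% propose(s)$key)
  expect_error(approve(s, top), "already decided")
  expect_error(reject(s, nxt), "already decided")
  expect_equal(nrow(propose(s, top_k = 5L)), 5L)
})

test_that("score ties break lexicographically by property then value URI", {
  # two annotations with identical counts everywhere -> identical scores
  A <- tkey("p1", "a"); B <- tkey("p2", "b")
  corp <- make_corpus(list(c(A, B), c(A, B)))
  feats <- list("1" = "(NN x)", "2" = "(NN x)")
  ms <- build_models(corp, feats, min_instances = 1L)
  cms <- initial_calibrations(ms, feats)
  s <- new_session("", cms)
  p <- propose(s)
  expect_equal(p$score[[1]], p$score[[2]])
  expect_equal(p$key, sort(c(A, B)))
})

test_that("filtering restricts to one property, search spans unmodeled options", {
  w <- session_world(52)
  s <- new_session(w$corpus$documents[[2]]$text, w$cms, w$corr, w$cc)
  prop <- propose(s)$property_uri[[1]]
  filt <- filter_by_property(s, prop)
  expect_true(all(filt$property_uri == prop))
  expect_true(all(diff(filt$score) <= 0))
  # search with empty query returns every undecided candidate
  all_hits <- search_annotations(s, "")
  expect_setequal(all_hits$key, setdiff(s$universe, c(s$approved, s$rejected)))
  # scored results come first
  expect_false(is.unsorted(rev(all_hits$has_model)))
  # a label unique to an unmodeled annotation is reachable by search
  if (length(w$ms$unmodeled)) {
    un <- w$ms$unmodeled[[1]]
    lab <- w$corpus$annotations$value_label[w$corpus$annotations$key == un]
    hits <- search_annotations(s, lab)
    expect_true(un %in% hits$key)
    expect_false(hits$has_model[hits$key == un])
  }
})

test_that("the simulated operator always collects exactly the reachable truth", {
  w <- session_world(53)
  for (d in w$corpus$documents[1:6]) {
    tr <- simulate_operator(d, w$cms, w$corr, w$cc)
    reachable <- intersect(d$annotations, names(w$ms$models))
    expect_equal(tr$positives, length(reachable))
    expect_equal(sum(tr$marks == "+"), tr$positives)
    expect_setequal(tr$unreachable, setdiff(d$annotations, names(w$ms$models)))
    expect_equal(length(tr$marks), length(tr$picked))
  }
})

test_that("operator traces are deterministic replays", {
  w <- session_world(54)
  d <- w$corpus$documents[[3]]
  t1 <- simulate_operator(d, w$cms, w$corr, w$cc)
  t2 <- simulate_operator(d, w$cms, w$corr, w$cc)
  expect_identical(t1$marks, t2$marks)
  expect_identical(t1$picked, t2$picked)
})

test_that("an adversarial planted candidate draws exactly one negative mark", {
  # annotation F's block appears in the probe text although F is absent
  A <- tkey("p1", "a"); B <- tkey("p2", "b"); F_ <- tkey("p3", "f")
  corp <- make_corpus(list(c(A, B), c(A, B), c(F_), c(F_)))
  feats <- list("1" = c("(NN ax)", "(NN bx)"), "2" = c("(NN ax)", "(NN bx)"),
                "3" = "(NN fx)", "4" = "(NN fx)")
  ms <- build_models(corp, feats, min_instances = 2L)
  cms <- initial_calibrations(ms, feats)
  probe <- new_document(9L, "", c(A, B))
  # probe text contains F's block and A's, but not B's: F outranks B
  cal <- drop(calibrate_scores(cms, score_documents(ms, list(doc = c("(NN ax)", "(NN fx)")))))
  tr <- simulate_operator(probe, cms, calibrated = cal)
  expect_equal(tr$positives, 2L)
  expect_equal(tr$negatives, 1L)
  expect_equal(tr$picked[tr$marks == "-"], F_)
  # brute-force replay: ranking by the calibrated scores directly
  expect_equal(tr$picked[[1]], names(sort(-cal))[[1]])
})

test_that("a constant scorer behaves like an arbitrary fixed ordering", {
  # all scores equal -> proposals in lexicographic order; with truth sets
  # placed uniformly at random, negatives match the closed-form expectation
  # for a random ordering: (m - k) * k / (k + 1)
  m_cand <- 12L; k_true <- 3L
  anns <- vapply(seq_len(m_cand), function(i) tkey(sprintf("p%02d", i), "v"), "")
  corp <- make_corpus(lapply(seq_len(m_cand), function(i) anns[[i]]))
  feats <- setNames(rep(list(character(0)), m_cand), as.character(seq_len(m_cand)))
  ms <- build_models(corp, feats, min_instances = 1L)
  cms <- calibrated_models(ms, a = setNames(rep(1, m_cand), anns),
                           b = setNames(rep(0, m_cand), anns))
  set.seed(99)
  negs <- replicate(100, {
    truth <- sample(anns, k_true)
    simulate_operator(new_document(1L, "", truth), cms)$negatives
  })
  expected <- (m_cand - k_true) * k_true / (k_true + 1)
  se <- sd(negs) / sqrt(length(negs))
  expect_lt(abs(mean(negs) - expected), 3 * se + 1e-9)
})

test_that("the frequency baseline is static, normalized and stably tied", {
  A <- tkey("p1", "a"); B <- tkey("p2", "b"); C <- tkey("p3", "c")
  corp <- make_corpus(list(c(A, B), c(A, C), c(A), c(B)))
  fb <- frequency_baseline(corp)
  expect_equal(fb$key[[1]], A)
  expect_equal(fb$frequency[[1]], 0.75)
  # equal counts tie-break lexicographically, stable across calls
  expect_equal(fb$key[2:3], sort(c(B, C)))
  expect_identical(fb, frequency_baseline(corp))
  expect_error(frequency_baseline(new_corpus(list())), "empty")
})

test_that("evaluate_corpus summarizes traces and degenerate corpora", {
  w <- session_world(55)
  empty <- new_corpus(list())
  ev0 <- evaluate_corpus(empty, w$cms)
  expect_equal(ev0$summary$n_documents, 0L)
  expect_equal(ev0$summary$mean_negatives, 0)
  one <- new_corpus(w$corpus$documents[1], w$corpus$annotations, w$corpus$labels)
  ev1 <- evaluate_corpus(one, w$cms, w$corr, w$cc, train = w$corpus)
  expect_length(ev1$traces, 1L)
  expect_equal(ev1$traces[[1]]$positives,
               length(intersect(w$corpus$documents[[1]]$annotations,
                                names(w$ms$models))))
  expect_true(!is.null(ev1$heat))
  f <- withr::local_tempfile()
  write_hitmiss(ev1, f)
  row <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(as.integer(row[[1]]), w$corpus$documents[[1]]$doc_id)
  expect_setequal(unique(row[-1]), intersect(c("+", "-"), row[-1]))
})

test_that("free-text annotations surface only in the RDF export", {
  w <- session_world(56)
  s <- new_session(w$corpus$documents[[1]]$text, w$cms)
  s <- add_free_text(s, "http://example.org/bao-test#pX", "novel target")
  expect_false(any(grepl("novel target", propose(s)$key)))
  g <- session_triples(s, 7)
  expect_true("novel target" %in% g$object[g$object_type == "string"])
})
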