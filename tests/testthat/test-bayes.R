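test_that("model counts match a hand count on a two-document corpus", {
  A <- tkey("p", "a")
  corp <- make_corpus(list(A, A))
  feats <- list("1" = "(NN b)", "2" = character(0))
  ms <- build_models(corp, feats, min_instances = 1L)
  m <- annotation_model(ms, A)
  expect_equal(m$P, 1.0)
  expect_equal(unname(m$A["(NN b)"]), 1)
  expect_equal(unname(m$T_n["(NN b)"]), 1)
  expect_equal(ms$n_train, 2L)
})

test_that("annotations below the modelability threshold are reported unmodeled", {
  A <- tkey("p", "a"); B <- tkey("p", "b")
  corp <- make_corpus(list(c(A, B), B))
  feats <- list("1" = "(NN x)", "2" = "(NN y)")
  ms <- build_models(corp, feats, min_instances = 2L)
  expect_named(ms$models, B)
  expect_equal(ms$unmodeled, A)
  expect_error(build_models(make_corpus(list()), list()), "empty")
})

test_that("raw_score evaluates the Laplacian-modified log-ratio sum", {
  # empty feature set: empty sum
  A <- tkey("p", "a")
  corp <- make_corpus(list(c(A), c(A), character(0), character(0)))
  feats <- list("1" = "(NN b)", "2" = "(NN b)", "3" = "(NN b)", "4" = character(0))
  ms <- build_models(corp, feats, min_instances = 1L)
  m <- annotation_model(ms, A)
  expect_identical(raw_score(m, character(0)), 0)
  # A_n = 2, T_n = 3, P = 0.5 -> ln(3 / 2.5)
  expect_equal(raw_score(m, "(NN b)"), log(3 / 2.5), tolerance = 1e-15)
  # unseen blocks contribute nothing
  expect_equal(raw_score(m, c("(NN b)", "(NN unseen)")), log(3 / 2.5),
               tolerance = 1e-15)
})

test_that("raw_score agrees with the brute-force counting oracle to 1e-12", {
  for (seed in 1:5) {
    world <- random_toy(seed)
    ms <- build_models(world$corpus, world$features, min_instances = 1L)
    probe <- sort(sample(world$blocks, 10))
    for (key in names(ms$models)) {
      got <- raw_score(annotation_model(ms, key), probe)
      want <- oracle_raw_score(world$corpus, world$features, key, probe)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("raw_score is additive over disjoint feature sets", {
  world <- random_toy(7)
  ms <- build_models(world$corpus, world$features, min_instances = 1L)
  m <- annotation_model(ms, names(ms$models)[[1]])
  f1 <- world$blocks[1:10]; f2 <- world$blocks[11:25]
  expect_equal(raw_score(m, union(f1, f2)),
               raw_score(m, f1) + raw_score(m, f2), tolerance = 1e-12)
})

test_that("each summand is positive exactly when the block is over-represented", {
  world <- random_toy(3)
  ms <- build_models(world$corpus, world$features, min_instances = 1L)
  for (key in names(ms$models)[1:3]) {
    m <- annotation_model(ms, key)
    for (b in world$blocks[1:10]) {
      if (!b %in% names(m$T_n)) next
      A_n <- if (b %in% names(m$A)) m$A[[b]] else 0
      s <- raw_score(m, b)
      expect_equal(s > 0, (A_n + 1) > (m$T_n[[b]] * m$P + 1))
    }
  }
})

test_that("score_documents matches per-document raw_score calls", {
  world <- random_toy(11)
  ms <- build_models(world$corpus, world$features, min_instances = 1L)
  S <- score_documents(ms, world$features)
  for (i in seq_along(world$features))
    for (key in names(ms$models))
      expect_equal(S[i, key],
                   raw_score(annotation_model(ms, key), world$features[[i]]),
                   tolerance = 1e-12)
})

test_that("loo_scores equals scoring under fully rebuilt leave-one-out models", {
  world <- random_toy(5, n_docs = 12L)
  ms <- build_models(world$corpus, world$features, min_instances = 1L)
  S <- loo_scores(ms, world$corpus, world$features)
  ids <- as.character(vapply(world$corpus$documents, `[[`, integer(1), "doc_id"))
  for (i in seq_along(ids)) {
    rest <- world$corpus$documents[-i]
    sub <- new_corpus(rest)
    sub_feats <- world$features[names(world$features) != ids[[i]]]
    ms_i <- build_models(sub, sub_feats, min_instances = 1L)
    for (key in names(ms$models)) {
      if (!key %in% names(ms_i$models)) next
      want <- raw_score(annotation_model(ms_i, key), world$features[[ids[[i]]]])
      expect_equal(S[i, key], want, tolerance = 1e-12)
    }
  }
})

test_that("the Mann-Whitney AUC matches exhaustive pair enumeration and pROC", {
  set.seed(42)
  scores <- c(rnorm(8), rnorm(12, 1))
  labels <- rep(c(TRUE, FALSE), c(8, 12))
  expect_equal(auc_mann_whitney(scores, labels), oracle_auc(scores, labels))
  skip_if_not_installed("pROC")
  proc_auc <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                             direction = "<")))
  expect_equal(auc_mann_whitney(scores, labels), proc_auc, tolerance = 1e-12)
  # constant scorer: exactly one half under the tie convention
  expect_equal(auc_mann_whitney(rep(1, 20), labels), 0.5)
})

test_that("leave-one-out ROC separates a uniquely marked annotation perfectly", {
  world <- planted_world(n_docs = 12L)
  r <- loo_roc(world$corpus, world$features, world$anns[[1]],
               min_instances = 1L)
  expect_equal(r$auc, 1.0)
  # AUC equals the pairwise-ordering oracle on the same fold scores
  expect_equal(r$auc, oracle_auc(r$scores, r$labels))
})

test_that("loo_roc rejects annotations that fall below threshold in a fold", {
  A <- tkey("p", "a"); B <- tkey("p", "b")
  corp <- make_corpus(list(c(A, B), c(A, B), B))
  feats <- list("1" = "(NN x)", "2" = "(NN y)", "3" = "(NN z)")
  expect_error(loo_roc(corp, feats, A, min_instances = 2L), "below 2")
})
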