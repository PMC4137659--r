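# Shared fixture builders and independent brute-force oracles. Oracles
# recount everything from scratch with naive loops so they stay independent
# of the vectorized implementation paths they check.

NS <- "http://example.org/bao-test#"

tkey <- function(p, v) ann_key(paste0(NS, p), paste0(NS, v))

# a corpus built directly from (id, annotations) pairs; texts optional
make_corpus <- function(ann_sets, texts = NULL, labels = character()) {
  docs <- lapply(seq_along(ann_sets), function(i) {
    new_document(if (is.null(names(ann_sets))) i else as.integer(names(ann_sets)[[i]]),
                 if (is.null(texts)) "" else texts[[i]],
                 ann_sets[[i]])
  })
  new_corpus(docs, labels = labels)
}

# random toy corpus with explicit feature sets (no NLP involved)
random_toy <- function(seed, n_docs = 20L, n_blocks = 30L, n_anns = 6L) {
  set.seed(seed)
  blocks <- sprintf("(NN tok%02d)", seq_len(n_blocks))
  anns <- vapply(seq_len(n_anns), function(i) tkey(sprintf("p%02d", i), "v"), "")
  ann_sets <- lapply(seq_len(n_docs), function(i)
    sample(anns, sample(1:4, 1)))
  feats <- lapply(seq_len(n_docs), function(i)
    sort(sample(blocks, sample(3:12, 1))))
  names(feats) <- as.character(seq_len(n_docs))
  list(corpus = make_corpus(ann_sets), features = feats,
       blocks = blocks, anns = anns)
}

# oracle: recount A_n, T_n, P from scratch and evaluate the score equation
oracle_raw_score <- function(corpus, features, annotation, doc_features) {
  ids <- as.character(vapply(corpus$documents, `[[`, integer(1), "doc_id"))
  n <- length(ids)
  has_ann <- vapply(corpus$documents, function(d) annotation %in% d$annotations,
                    logical(1))
  P <- sum(has_ann) / n
  seen <- unique(unlist(features, use.names = FALSE))
  total <- 0
  for (b in doc_features) {
    if (!b %in% seen) next
    T_n <- sum(vapply(ids, function(i) b %in% features[[i]], logical(1)))
    A_n <- sum(vapply(seq_along(ids), function(k)
      has_ann[[k]] && b %in% features[[ids[[k]]]], logical(1)))
    total <- total + log((A_n + 1) / (T_n * P + 1))
  }
  total
}

# oracle: pairwise-ordering separation by exhaustive pair enumeration
oracle_separation <- function(S, present) {
  fracs <- c()
  for (d in seq_len(nrow(S))) {
    pres <- which(present[d, ]); abs_ <- which(!present[d, ])
    if (!length(pres) || !length(abs_)) next
    correct <- 0
    for (i in pres) for (k in abs_) {
      if (S[d, i] > S[d, k]) correct <- correct + 1
      else if (S[d, i] == S[d, k]) correct <- correct + 0.5
    }
    fracs <- c(fracs, correct / (length(pres) * length(abs_)))
  }
  mean(fracs)
}

# oracle: AUC by exhaustive pair enumeration
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# all subtrees of a pos_tree by naive recursion (oracle for extract_blocks)
oracle_subtrees <- function(tree) {
  out <- list(tree)
  for (ch in tree$children) out <- c(out, oracle_subtrees(ch))
  out
}

# A tiny deterministic training world with hand-planted block/annotation
# structure: each annotation has one dedicated block that appears in all
# and only its documents, so rankings are fully predictable.
planted_world <- function(n_docs = 12L, n_anns = 4L) {
  anns <- vapply(seq_len(n_anns), function(i) tkey(sprintf("P%d", i), sprintf("V%d", i)), "")
  blocks <- sprintf("(NN planted%d)", seq_len(n_anns))
  ann_sets <- list(); feats <- list()
  for (d in seq_len(n_docs)) {
    which_anns <- which((d + seq_len(n_anns)) %% 2 == 0)  # alternating halves
    if (!length(which_anns)) which_anns <- 1L
    ann_sets[[d]] <- anns[which_anns]
    feats[[as.character(d)]] <- sort(c(blocks[which_anns], "(NN filler)"))
  }
  list(corpus = make_corpus(ann_sets), features = feats,
       anns = anns, blocks = blocks)
}

# shared strong-preset pipeline at the generator's default (paper-like)
# scale, built lazily once per test run
strong_env <- new.env(parent = emptyenv())
strong_pipeline <- function() {
  if (!is.null(strong_env$fit)) return(strong_env$fit)
  cfg <- generator_config(n_documents = 1020L, seed = 20260901L)
  gen <- generate_corpus(cfg)
  corpus <- gen$corpus
  train <- new_corpus(corpus$documents[1:1000], corpus$annotations, corpus$labels)
  test <- new_corpus(corpus$documents[1001:1020], corpus$annotations, corpus$labels)
  feats <- corpus_features(train)
  ms <- build_models(train, feats)
  cms <- optimize_calibration(ms, train, feats, sweeps = 10L, seed = 1L)
  corr <- build_correlation_models(train)
  corr_cal <- calibrate_correlation(corr, train)
  strong_env$fit <- list(gen = gen, corpus = corpus, features = feats,
                         train = train, test = test, ms = ms, cms = cms,
                         corr = corr, corr_cal = corr_cal)
  strong_env$fit
}

# strong preset reduced to one annotation per document with no background:
# the regime where an annotation's unique phrases are the only systematic
# signal, so leave-one-out recall is exact
unique_phrase_world <- function(seed = 7L) {
  cfg <- generator_config(n_documents = 80L, n_properties = 12L,
                          values_per_property = 4L,
                          annotations_per_doc = c(1L, 1L),
                          background_phrases = 0L, seed = seed)
  gen <- generate_corpus(cfg)
  list(gen = gen, corpus = gen$corpus,
       features = corpus_features(gen$corpus))
}

# small fast world for optimizer property tests
small_world <- function(seed) {
  cfg <- generator_config(n_documents = 50L, n_properties = 10L,
                          values_per_property = 6L,
                          annotations_per_doc = c(5L, 8L),
                          background_phrases = 20L, seed = seed)
  gen <- generate_corpus(cfg)
  feats <- corpus_features(gen$corpus)
  ms <- build_models(gen$corpus, feats)
  list(gen = gen, corpus = gen$corpus, features = feats, ms = ms)
}

CDD <- "http://www.collaborativedrug.com/bao/curation.owl#"
BAO <- "http://www.bioassayontology.org/bao#"
RDFS <- "http://www.w3.org/2000/01/rdf-schema#"

# A small synthetic annotation graph shaped like the assay-kit / instrument
# query examples: constructed in code, with labels, so label-join queries
# can be verified against hand-derived answers.
synthetic_graph <- function() {
  kit_prop <- paste0(BAO, "BAO_0002663")
  kit_val <- paste0(BAO, "KIT_0001")
  instr_prop <- paste0(BAO, "BAO_0002865")
  g <- rdf_bind(
    to_triples(933, ann_key(kit_prop, kit_val)),
    to_triples(940, ann_key(kit_prop, kit_val)),
    to_triples(1080, c(ann_key(kit_prop, kit_val),
                       ann_key(paste0(BAO, "BAO_0002855"), paste0(BAO, "BAO_0000110")))),
    to_triples(622, c(ann_key(paste0(BAO, "BAO_0002855"), paste0(BAO, "BAO_0000110")),
                      ann_key(paste0(BAO, "BAO_0000196"), paste0(BAO, "BAO_0000091")),
                      ann_key(paste0(BAO, "BAO_0000207"), paste0(BAO, "BAO_0000363")),
                      ann_key(instr_prop, paste0(BAO, "INSTR_ENVISION")))),
    to_triples(1986, c(ann_key(paste0(BAO, "BAO_0002855"), paste0(BAO, "BAO_0000110")),
                       ann_key(paste0(BAO, "BAO_0000196"), paste0(BAO, "BAO_0000091")),
                       ann_key(paste0(BAO, "BAO_0000207"), paste0(BAO, "BAO_0000363")),
                       ann_key(instr_prop, paste0(BAO, "INSTR_PHERASTAR")))),
    label_triples(c(
      setNames("has assay kit", kit_prop),
      setNames("HTRF cAMP Detection Kit", kit_val),
      setNames("EnVision Multilabel Reader", paste0(BAO, "INSTR_ENVISION")),
      setNames("PHERAstar Plus", paste0(BAO, "INSTR_PHERASTAR")))))
  g
}
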