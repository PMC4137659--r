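# Synthetic corpora with the statistical structure the method assumes:
# documents carry 20-30 property:value annotations drawn with planted
# pairwise couplings, and their text is built from multi-word phrase
# inventories attached to each annotation, plus background phrases common
# to all documents. Multi-token phrases (not bare unigrams) carry the
# signal, so chunked POS blocks are the informative features.

#' Configuration for the synthetic corpus generator
#'
#' @param n_documents Number of documents (default 1000, the corpus
#'   scale the method targets: roughly a thousand curated assays).
#' @param n_properties Number of annotation properties (default 30).
#' @param values_per_property Values per property (default 4, a small
#'   controlled vocabulary per property so that every value accumulates
#'   enough training instances to model at the default corpus scale).
#' @param annotations_per_doc Integer range, annotations per document
#'   (default `c(20, 30)`; capped at `n_properties`).
#' @param phrases_per_annotation Phrases in each annotation's inventory
#'   (default 3).
#' @param background_phrases Size of the shared background phrase pool
#'   (default 150).
#' @param signal_strength `"strong"`, `"medium"` or `"sparse"`: how
#'   exclusively phrases attach to annotations and how reliably they are
#'   emitted. Strong: disjoint inventories and every phrase of every
#'   present annotation is emitted. Medium: each phrase emitted with
#'   probability 0.65 (at least one per present annotation, since an
#'   annotation derived from a text implies the text mentions it) and 30%
#'   of non-lead phrases are shared with a sibling value of the same
#'   property. Sparse: emission 0.35 and 50% sharing.
#' @param co_occurrence_pairs Data frame with columns `a`, `b` (annotation
#'   keys) and `prob`: when `a` is present, `b` is forced present with
#'   exactly probability `prob` (and forced absent otherwise), so the
#'   conditional P(b | a) equals `prob`.
#' @param n_archetypes Number of latent assay families (default 0, i.e.
#'   disabled: properties are sampled independently). Real
#'   assay corpora are strongly clustered: assays of the same family share
#'   most annotation values, which is what makes annotation sets highly
#'   non-orthogonal. Each document draws one archetype and takes the
#'   archetype's preferred value for each chosen property with probability
#'   `archetype_fidelity`, otherwise a popularity-weighted random value.
#'   `n_archetypes = 0` disables clustering (independent properties).
#' @param archetype_fidelity Probability of following the archetype's
#'   preferred value (default 0.8).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `bao_generator_config`.
#' @export
generator_config <- function(n_documents = 1000L, n_properties = 30L,
                             values_per_property = 4L,
                             annotations_per_doc = c(20L, 30L),
                             phrases_per_annotation = 3L,
                             background_phrases = 150L,
                             signal_strength = c("strong", "medium", "sparse"),
                             co_occurrence_pairs = NULL,
                             n_archetypes = 0L,
                             archetype_fidelity = 0.8,
                             seed = 1L) {
  signal_strength <- match.arg(signal_strength)
  stopifnot(n_documents >= 0L, n_properties >= 1L, values_per_property >= 1L,
            length(annotations_per_doc) == 2L,
            annotations_per_doc[[1]] >= 1L,
            annotations_per_doc[[2]] >= annotations_per_doc[[1]],
            phrases_per_annotation >= 1L, background_phrases >= 0L,
            n_archetypes >= 0L, archetype_fidelity >= 0, archetype_fidelity <= 1)
  if (!is.null(co_occurrence_pairs)) {
    stopifnot(is.data.frame(co_occurrence_pairs),
              all(c("a", "b", "prob") %in% names(co_occurrence_pairs)),
              all(co_occurrence_pairs$prob >= 0),
              all(co_occurrence_pairs$prob <= 1))
  }
  structure(list(n_documents = as.integer(n_documents),
                 n_properties = as.integer(n_properties),
                 values_per_property = as.integer(values_per_property),
                 annotations_per_doc = as.integer(annotations_per_doc),
                 phrases_per_annotation = as.integer(phrases_per_annotation),
                 background_phrases = as.integer(background_phrases),
                 signal_strength = signal_strength,
                 co_occurrence_pairs = co_occurrence_pairs,
                 n_archetypes = as.integer(n_archetypes),
                 archetype_fidelity = archetype_fidelity,
                 seed = as.integer(seed)),
            class = "bao_generator_config")
}

SYN_NS <- "http://www.bioassayontology.org/bao#"

syn_property_uri <- function(j) sprintf("%sSYNP%03d", SYN_NS, j)
syn_value_uri <- function(j, v) sprintf("%sSYNP%03dV%02d", SYN_NS, j, v)

#' Annotation key of a synthetic property/value index pair
#'
#' @param property,value 1-based indices into the generator's grid.
#' @return Annotation key.
#' @export
syn_annotation_key <- function(property, value) {
  ann_key(syn_property_uri(property), syn_value_uri(property, value))
}

# Pronounceable deterministic pseudo-words.
syn_word <- function(n = 1L, suffix = "") {
  on1 <- c("b", "c", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z",
           "br", "cl", "cr", "dr", "fl", "gr", "pl", "pr", "st", "str", "tr", "th")
  vow <- c("a", "e", "i", "o", "u", "ia", "io", "ou")
  vapply(seq_len(n), function(i) {
    k <- sample(2:3, 1)
    w <- paste0(paste0(sample(on1, k, replace = TRUE),
                       sample(vow, k, replace = TRUE), collapse = ""), suffix)
    w
  }, "")
}

syn_phrase <- function() {
  # 2-5 tokens; noun compounds with occasional adjectives / function words
  template <- sample(c("NN NN", "JJ NN", "JJ NN NN", "NN NN NN",
                       "DT JJ NN NN", "NN IN NN"), 1,
                     prob = c(0.25, 0.2, 0.2, 0.15, 0.1, 0.1))
  toks <- strsplit(template, " ", fixed = TRUE)[[1]]
  words <- vapply(toks, function(t) {
    switch(t,
           NN = syn_word(),
           JJ = syn_word(suffix = sample(c("ic", "al", "ous", "based"), 1)),
           DT = sample(c("the", "a"), 1),
           IN = sample(c("of", "with", "in"), 1))
  }, "")
  paste(words, collapse = " ")
}

# Each phrase is bound to one fixed carrier sentence at inventory-creation
# time: curated assay descriptions reuse standard phrasing nearly verbatim
# across assays, so the sentence form of a fact is stable, not resampled
# per document.
syn_sentence <- function(phrase) {
  template <- sample(c("The assay uses %s.", "Each well contains %s.",
                       "The protocol measures %s.",
                       "Samples were incubated with %s.",
                       "Activity was monitored by %s."), 1)
  sprintf(template, phrase)
}

#' Generate a synthetic annotated corpus
#'
#' Documents receive annotation sets sampled property-by-property (a
#' uniform count in `annotations_per_doc`, one value per chosen property
#' with skewed value popularity), then planted couplings are applied in
#' order. Text is one sentence per emitted annotation phrase plus
#' background sentences. Byte-identical output for identical configs.
#'
#' @param config A `bao_generator_config`.
#' @return List with elements `corpus` (a `bao_corpus`) and `truth`
#'   (per-annotation phrase inventories, the unique phrase of each
#'   annotation, background phrases, and the config).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "bao_generator_config"))
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  P <- cfg$n_properties; V <- cfg$values_per_property
  keys <- character(0)
  for (j in seq_len(P)) for (v in seq_len(V))
    keys <- c(keys, syn_annotation_key(j, v))
  key_grid <- matrix(keys, nrow = V)           # V x P, column per property

  if (!is.null(cfg$co_occurrence_pairs)) {
    unknown <- setdiff(c(cfg$co_occurrence_pairs$a, cfg$co_occurrence_pairs$b), keys)
    if (length(unknown))
      stop("co_occurrence_pairs name unknown annotation(s): ",
           paste(unknown, collapse = ", "))
  }

  # phrase inventories; each phrase is bound to one carrier sentence
  emit_prob <- switch(cfg$signal_strength, strong = 1, medium = 0.65, sparse = 0.35)
  share_prob <- switch(cfg$signal_strength, strong = 0, medium = 0.3, sparse = 0.5)
  phrases <- list(); unique_phrase <- character(0)
  for (k in keys) {
    inv <- vapply(seq_len(cfg$phrases_per_annotation), function(i) syn_phrase(), "")
    phrases[[k]] <- inv
    unique_phrase[[k]] <- inv[[1]]
  }
  if (share_prob > 0) {
    for (j in seq_len(P)) for (v in seq_len(V)) {
      k <- key_grid[v, j]
      sib <- key_grid[if (v == V) 1L else v + 1L, j]
      for (i in seq_len(cfg$phrases_per_annotation)[-1]) {
        if (runif(1) < share_prob) phrases[[k]][[i]] <- phrases[[sib]][[1]]
      }
    }
  }
  background <- vapply(seq_len(cfg$background_phrases), function(i) syn_phrase(), "")
  sentence_of <- lapply(phrases, function(inv) vapply(inv, syn_sentence, ""))
  bg_sentence <- vapply(background, syn_sentence, "")

  value_weights <- seq(1.5, 0.5, length.out = V)  # mild popularity skew
  value_weights <- value_weights / sum(value_weights)
  lo <- min(cfg$annotations_per_doc[[1]], P)
  hi <- min(cfg$annotations_per_doc[[2]], P)
  archetypes <- if (cfg$n_archetypes > 0L)
    matrix(sample(seq_len(V), cfg$n_archetypes * P, replace = TRUE,
                  prob = value_weights), nrow = cfg$n_archetypes)
  else NULL

  docs <- vector("list", cfg$n_documents)
  for (d in seq_len(cfg$n_documents)) {
    k_count <- if (hi > lo) sample(lo:hi, 1) else lo
    props <- sort(sample(seq_len(P), k_count))
    vals <- sample(seq_len(V), k_count, replace = TRUE, prob = value_weights)
    if (!is.null(archetypes)) {
      arch <- sample(cfg$n_archetypes, 1)
      follow <- runif(k_count) < cfg$archetype_fidelity
      vals[follow] <- archetypes[arch, props[follow]]
    }
    anns <- key_grid[cbind(vals, props)]
    if (!is.null(cfg$co_occurrence_pairs)) {
      for (r in seq_len(nrow(cfg$co_occurrence_pairs))) {
        pa <- cfg$co_occurrence_pairs$a[[r]]
        pb <- cfg$co_occurrence_pairs$b[[r]]
        pc <- cfg$co_occurrence_pairs$prob[[r]]
        if (pa %in% anns) {
          prop_b <- which(apply(key_grid, 2, function(col) pb %in% col))
          anns <- anns[!anns %in% key_grid[, prop_b]]   # clear b's property
          if (runif(1) < pc) anns <- c(anns, pb)
        }
      }
    }
    anns <- sort(unique(anns))
    sentences <- character(0)
    for (k in anns) {
      emitted <- runif(cfg$phrases_per_annotation) < emit_prob
      if (cfg$signal_strength != "strong") emitted[[1]] <- emitted[[1]] ||
          !any(emitted)                     # at least one phrase per fact
      sentences <- c(sentences, sentence_of[[k]][emitted])
    }
    n_bg <- if (length(background)) sample(3:6, 1) else 0L
    if (n_bg > 0L)
      sentences <- c(sentences,
                     bg_sentence[sample(length(bg_sentence), min(n_bg, length(bg_sentence)))])
    sentences <- sample(sentences)               # shuffle sentence order
    docs[[d]] <- new_document(1000L + d, paste(sentences, collapse = " "), anns)
  }

  labels <- syn_labels(P, V)
  truth <- list(phrases = phrases, unique_phrase = unique_phrase,
                background = background, archetypes = archetypes, config = cfg)
  list(corpus = new_corpus(docs, labels = labels), truth = truth)
}

syn_labels <- function(P, V) {
  labels <- character(0)
  for (j in seq_len(P)) {
    labels[[syn_property_uri(j)]] <- sprintf("synthetic property %03d", j)
    for (v in seq_len(V))
      labels[[syn_value_uri(j, v)]] <- sprintf("synthetic value %03d-%02d", j, v)
  }
  labels
}

#' Write a generated corpus as a fixture
#'
#' Emits the simple corpus dialect (or Turtle) via [write_corpus()]; the
#' result round-trips through [read_corpus_fixture()] to an equal corpus.
#'
#' @param corpus A `bao_corpus`.
#' @param path Output directory (simple) or `.ttl` file path.
#' @param format `"simple"` or `"ttl"`.
#' @return Invisibly, the main path written.
#' @export
write_fixture <- function(corpus, path, format = c("simple", "ttl")) {
  write_corpus(corpus, path, format)
}
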