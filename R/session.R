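# The interactive annotation workflow engine. A session holds one
# document's text features, the calibrated models, correlation models and
# the running approved/rejected state; proposals are the modeled
# candidates not yet decided, ranked by correlation-adjusted calibrated
# score, ties broken lexicographically by (property URI, value URI).

#' Open an annotation session for a document text
#'
#' @param text Plain assay description text.
#' @param cms A `bao_calibrated_models`.
#' @param corr A `bao_corr_models` (optional; `NULL` disables correlation
#'   rescoring).
#' @param corr_cal A `bao_corr_calibration` matching `corr`.
#' @param max_tokens Block size limit used at feature extraction (must
#'   match training).
#' @param extra_candidates Character vector of additional (possibly
#'   unmodeled) annotation keys to expose to search/filter, beyond the
#'   model set's modeled + unmodeled annotations.
#' @param calibrated Optional precomputed named vector of calibrated text
#'   scores for this document (one per modeled annotation); skips feature
#'   scoring, which batch evaluation uses to score a whole corpus in one
#'   pass.
#' @param corr_W Optional precomputed [corr_weight_matrix()] to share
#'   across sessions.
#' @return A `bao_session`.
#' @export
new_session <- function(text, cms, corr = NULL, corr_cal = NULL,
                        max_tokens = 8L, extra_candidates = character(),
                        calibrated = NULL, corr_W = NULL) {
  ms <- cms$models
  modeled <- names(ms$models)
  universe <- sort(unique(c(modeled, ms$unmodeled, extra_candidates)))
  if (is.null(calibrated)) {
    features <- text_features(text, max_tokens)
    raw <- score_documents(ms, list(doc = features))
    calibrated <- drop(calibrate_scores(cms, raw))
  } else {
    stopifnot(all(modeled %in% names(calibrated)))
    features <- character(0)
  }
  if (is.null(corr_W) && !is.null(corr)) corr_W <- corr_weight_matrix(corr)
  structure(list(text = text, features = features,
                 cms = cms, corr = corr, corr_cal = corr_cal,
                 corr_W = corr_W,
                 universe = universe, modeled = modeled,
                 calibrated = calibrated,
                 annotations = ms$annotations,
                 approved = character(0), rejected = character(0),
                 free_text = data.frame(property_uri = character(0),
                                        text = character(0))),
            class = "bao_session")
}

#' @export
print.bao_session <- function(x, ...) {
  cat(sprintf("<bao_session> %d candidates (%d modeled), %d approved, %d rejected\n",
              length(x$universe), length(x$modeled),
              length(x$approved), length(x$rejected)))
  invisible(x)
}

session_scores <- function(session, candidates) {
  scores <- session$calibrated[candidates]
  use_corr <- length(session$approved) > 0 && !is.null(session$corr) &&
    !is.null(session$corr_cal) && session$corr_cal$w > 0
  if (use_corr) {
    cc <- session$corr_cal
    W <- session$corr_W
    have <- intersect(candidates, rownames(W))
    appr <- intersect(session$approved, colnames(W))
    if (length(have) && length(appr)) {
      corr_raw <- rowSums(W[have, appr, drop = FALSE])
      scores[have] <- adjusted_score(scores[have], corr_raw,
                                     a = cc$a[have], b = cc$b[have], w = cc$w)
    }
  }
  scores
}

rank_proposals <- function(session, candidates) {
  ann <- ann_unkey(candidates)
  scores <- session_scores(session, candidates)
  ord <- order(-scores, ann$property_uri, ann$value_uri)
  out <- ann[ord, c("key", "property_uri", "value_uri"), drop = FALSE]
  out$score <- unname(scores[ord])
  out$has_model <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Ranked annotation proposals
#'
#' Candidates are the modeled annotations minus anything already approved
#' or rejected, scored by the correlation-adjusted calibrated score given
#' the current approved set, sorted highest first (ties broken by property
#' then value URI).
#'
#' @param session A `bao_session`.
#' @param top_k Number of proposals to return (default all).
#' @return Data frame with columns `key`, `property_uri`, `value_uri`,
#'   `score`, `has_model`.
#' @export
propose <- function(session, top_k = Inf) {
  candidates <- setdiff(session$modeled, c(session$approved, session$rejected))
  out <- rank_proposals(session, candidates)
  if (is.finite(top_k)) out <- head(out, top_k)
  out
}

decide <- function(session, annotation, what) {
  if (annotation %in% session$approved || annotation %in% session$rejected)
    stop("annotation already decided: ", annotation)
  session[[what]] <- c(session[[what]], annotation)
  session
}

#' Approve or reject an annotation
#'
#' Approving grows the approved set (which feeds correlation rescoring);
#' rejecting permanently excludes a candidate. Deciding the same
#' annotation twice is an error.
#'
#' @param session A `bao_session`.
#' @param annotation Annotation key.
#' @return The updated session.
#' @export
approve <- function(session, annotation) decide(session, annotation, "approved")

#' @rdname approve
#' @export
reject <- function(session, annotation) decide(session, annotation, "rejected")

#' Record a free-text annotation
#'
#' For concepts absent from the ontology the curator may attach plain text
#' under a property; it surfaces only in RDF output, as a string literal.
#'
#' @param session A `bao_session`.
#' @param property_uri Property URI.
#' @param text Literal text.
#' @return The updated session.
#' @export
add_free_text <- function(session, property_uri, text) {
  session$free_text <- rbind(session$free_text,
                             data.frame(property_uri = property_uri, text = text))
  session
}

#' Filter proposals by property
#'
#' @param session A `bao_session`.
#' @param property_uri Property URI to keep.
#' @return Ranked proposals restricted to the property (undecided modeled
#'   candidates only).
#' @export
filter_by_property <- function(session, property_uri) {
  out <- propose(session)
  out[out$property_uri == property_uri, , drop = FALSE]
}

#' Search all candidates by label
#'
#' Case-insensitive substring search over property and value labels, across
#' the whole candidate universe -- including unmodeled annotations, which
#' carry no score (`has_model = FALSE`) and sort after all scored results.
#' An empty query returns every undecided candidate.
#'
#' @param session A `bao_session`.
#' @param query Search string.
#' @return Data frame like [propose()], with `score = NA` for unmodeled hits.
#' @export
search_annotations <- function(session, query = "") {
  candidates <- setdiff(session$universe, c(session$approved, session$rejected))
  tab <- session$annotations
  m <- match(candidates, tab$key)
  plab <- ifelse(is.na(m), "", tab$property_label[m])
  vlab <- ifelse(is.na(m), "", tab$value_label[m])
  if (nzchar(query)) {
    hit <- grepl(query, paste(plab, vlab), ignore.case = TRUE, fixed = FALSE)
    candidates <- candidates[hit]
  }
  modeled <- intersect(candidates, session$modeled)
  unmodeled <- setdiff(candidates, modeled)
  scored <- rank_proposals(session, modeled)
  un <- ann_unkey(sort(unmodeled))[, c("key", "property_uri", "value_uri"), drop = FALSE]
  un$score <- rep(NA_real_, nrow(un))
  un$has_model <- rep(FALSE, nrow(un))
  out <- rbind(scored, un)
  rownames(out) <- NULL
  out
}

#' Export a session's decisions as RDF triples
#'
#' @param session A `bao_session`.
#' @param doc_id Assay identifier for the document URI.
#' @param base_uri Document URI namespace.
#' @return An `rdf_graph` (see [to_triples()]).
#' @export
session_triples <- function(session, doc_id, base_uri = CDD_NS) {
  to_triples(doc_id, approved = session$approved,
             free_text = session$free_text, base_uri = base_uri)
}

# --- evaluation harness -------------------------------------------------

#' Frequency-ranking null baseline
#'
#' Ranks every training annotation by the fraction of training documents it
#' occurs in (an annotation in 100 of 698 documents scores 0.143); the same
#' order is proposed for every document regardless of its text. Ties break
#' lexicographically by key, stable across calls.
#'
#' @param train Training `bao_corpus`.
#' @return Data frame with columns `key`, `frequency`, sorted.
#' @export
frequency_baseline <- function(train) {
  n <- n_documents(train)
  if (n == 0L) stop("frequency_baseline is undefined for an empty corpus")
  counts <- annotation_counts(train)
  keys <- sort(names(counts))
  out <- data.frame(key = keys, frequency = unname(counts[keys]) / n)
  out <- out[order(-out$frequency, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate an expert operator on one document
#'
#' Replays the evaluation protocol: repeatedly take the current
#' highest-ranked proposal; if it is a true annotation record a positive
#' mark and approve it (feeding correlation rescoring), otherwise record a
#' negative mark and reject it. The loop stops once every true annotation
#' inside the candidate universe has been approved, so the number of
#' positive marks always equals the number of reachable true annotations.
#'
#' @param document A `bao_document` (its annotation set is the truth).
#' @param cms A `bao_calibrated_models`.
#' @param corr,corr_cal Correlation models and calibration (optional).
#' @param max_tokens Feature block size limit.
#' @param baseline Optional static ranking (a `frequency_baseline()` data
#'   frame); when given, scores are the document-independent frequencies
#'   and the models are ignored.
#' @param calibrated,corr_W Optional precomputed scores / correlation
#'   weights (see [new_session()]).
#' @return A `bao_trace`: `doc_id`, `marks` (character vector of `"+"` /
#'   `"-"` in pick order), `picked` (annotation keys in pick order),
#'   `positives`, `negatives`, and `unreachable` (true annotations outside
#'   the candidate universe).
#' @export
simulate_operator <- function(document, cms, corr = NULL, corr_cal = NULL,
                              max_tokens = 8L, baseline = NULL,
                              calibrated = NULL, corr_W = NULL) {
  truth <- document$annotations
  if (is.null(baseline)) {
    session <- new_session(document$text, cms, corr, corr_cal, max_tokens,
                           calibrated = calibrated, corr_W = corr_W)
    universe <- session$modeled
  } else {
    universe <- baseline$key
  }
  reachable <- intersect(truth, universe)
  marks <- character(0); picked <- character(0)
  if (is.null(baseline)) {
    while (!all(reachable %in% session$approved)) {
      top <- propose(session, top_k = 1L)
      if (nrow(top) == 0L) break            # defensive; cannot happen
      key <- top$key[[1]]
      if (key %in% reachable) {
        marks <- c(marks, "+"); session <- approve(session, key)
      } else {
        marks <- c(marks, "-"); session <- reject(session, key)
      }
      picked <- c(picked, key)
    }
  } else {
    pending <- baseline$key                  # static order, fixed upfront
    found <- 0L
    for (key in pending) {
      if (found == length(reachable)) break
      if (key %in% reachable) {
        marks <- c(marks, "+"); found <- found + 1L
      } else {
        marks <- c(marks, "-")
      }
      picked <- c(picked, key)
    }
  }
  structure(list(doc_id = document$doc_id, marks = marks, picked = picked,
                 positives = sum(marks == "+"), negatives = sum(marks == "-"),
                 unreachable = setdiff(truth, universe)),
            class = "bao_trace")
}

#' @export
print.bao_trace <- function(x, ...) {
  cat(sprintf("<bao_trace> doc %d: %s (%d+, %d-, %d unreachable)\n",
              x$doc_id, paste(x$marks, collapse = ""), x$positives,
              x$negatives, length(x$unreachable)))
  invisible(x)
}

trace_early_precision <- function(trace) {
  # fraction of reachable true annotations found before the first miss
  if (trace$positives == 0L) return(0)
  first_miss <- match("-", trace$marks)
  if (is.na(first_miss)) return(1)
  sum(trace$marks[seq_len(first_miss - 1L)] == "+") / trace$positives
}

#' Evaluate models over a corpus with the simulated operator
#'
#' Runs [simulate_operator()] on every document and summarizes: the mean
#' fraction of true annotations found before the first miss
#' (early precision), the mean number of negative marks per document, and
#' per-annotation training-count weights for heatmap coloring of poorly
#' covered models.
#'
#' @param test `bao_corpus` to evaluate.
#' @param cms,corr,corr_cal Models as in [simulate_operator()].
#' @param train Optional training corpus; when given, per-annotation
#'   training counts are reported as heatmap weights.
#' @param max_tokens Feature block size limit.
#' @param baseline Optional static ranking (see [simulate_operator()]).
#' @return A `bao_evaluation`: `traces` (list of `bao_trace`), `summary`
#'   (data frame), and `heat` (named training counts, or `NULL`).
#' @export
evaluate_corpus <- function(test, cms, corr = NULL, corr_cal = NULL,
                            train = NULL, max_tokens = 8L, baseline = NULL) {
  cal_matrix <- NULL
  corr_W <- if (!is.null(corr) && is.null(baseline)) corr_weight_matrix(corr)
  if (is.null(baseline) && n_documents(test) > 0L) {
    feats <- corpus_features(test, max_tokens)
    raw <- score_documents(cms$models, feats)
    cal_matrix <- calibrate_scores(cms, raw)
  }
  traces <- lapply(seq_along(test$documents), function(i)
    simulate_operator(test$documents[[i]], cms = cms, corr = corr,
                      corr_cal = corr_cal, max_tokens = max_tokens,
                      baseline = baseline,
                      calibrated = if (!is.null(cal_matrix)) cal_matrix[i, ],
                      corr_W = corr_W))
  n <- length(traces)
  summary <- data.frame(
    n_documents = n,
    mean_early_precision = if (n) mean(vapply(traces, trace_early_precision, 0)) else 0,
    mean_negatives = if (n) mean(vapply(traces, `[[`, 0, "negatives")) else 0,
    mean_positives = if (n) mean(vapply(traces, `[[`, 0, "positives")) else 0,
    total_unreachable = sum(vapply(traces, function(t) length(t$unreachable), 0L)))
  heat <- if (!is.null(train)) annotation_counts(train) else NULL
  structure(list(traces = traces, summary = summary, heat = heat),
            class = "bao_evaluation")
}

#' @export
print.bao_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<bao_evaluation> %d documents: early precision %.3f, mean negatives %.2f, mean positives %.2f\n",
              s$n_documents, s$mean_early_precision, s$mean_negatives,
              s$mean_positives))
  invisible(x)
}

#' Export hit/miss traces as delimited text
#'
#' One row per document: the doc id followed by the ordered `+`/`-` marks,
#' tab-separated -- the flat-file form of a hit/miss matrix plot.
#'
#' @param evaluation A `bao_evaluation`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_hitmiss <- function(evaluation, path) {
  lines <- vapply(evaluation$traces, function(t)
    paste(c(t$doc_id, t$marks), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
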