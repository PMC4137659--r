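# Per-annotation Laplacian-modified naive Bayes scorers over POS-block
# features:
#
#   score = sum_n ln[ (A_n + 1) / (T_n * P + 1) ]
#
# where n runs over the blocks of the document that were seen in training,
# A_n is the number of training documents containing both the block and the
# annotation, T_n the number of training documents containing the block,
# and P the fraction of training documents carrying the annotation. Sums of
# logs avoid numeric underflow; the result is a rank score with arbitrary
# scale, not a probability.
#
# Storage note: realistic corpora have large annotation vocabularies where
# most annotations are rare, so each model's A_n table is sparse (almost
# all blocks never co-occur with the annotation). Models store only the
# non-zero A_n entries; the shared T_n table is dense. Scoring across many
# models materializes the dense weight matrix in column chunks to bound
# memory.

#' Build the per-annotation Bayes models of a training corpus
#'
#' One model is built for every annotation occurring in at least
#' `min_instances` training documents; rarer annotations are recorded as
#' unmodeled (they can still surface in a session via search). Counts are
#' document-level presence/absence of each distinct POS block.
#'
#' @param train Training `bao_corpus`.
#' @param features Named list (by `doc_id`) of feature sets, e.g. from
#'   [corpus_features()].
#' @param min_instances Modelability threshold (default 2).
#' @param backend_tag Identity of the NLP backend the features came from.
#' @return A `bao_model_set`: per-annotation priors and sparse `A_n`
#'   counts, the shared `T_n` block table, `n_train`, plus the unmodeled
#'   annotations.
#' @export
build_models <- function(train, features, min_instances = 2L,
                         backend_tag = nlp_backend_tag()) {
  if (n_documents(train) == 0L) stop("cannot build models from an empty corpus")
  stopifnot(min_instances >= 1L)
  ids <- as.character(doc_ids(train))
  missing <- setdiff(ids, names(features))
  if (length(missing))
    stop("no FeatureSet for document(s): ", paste(head(missing, 5), collapse = ", "))
  features <- features[ids]

  blocks <- sort(unique(unlist(features, use.names = FALSE)))
  X <- incidence_matrix(features, blocks)          # docs x blocks, 0/1
  T_n <- Matrix::colSums(X)

  counts <- annotation_counts(train)
  modeled <- names(counts)[counts >= min_instances]
  unmodeled <- setdiff(names(counts), modeled)
  n <- length(ids)

  Y <- ann_incidence_matrix(train, modeled)        # docs x annotations
  A <- Matrix::crossprod(X, Y)                     # blocks x annotations, sparse
  A <- methods::as(A, "CsparseMatrix")
  models <- vector("list", length(modeled))
  for (j in seq_along(modeled)) {
    rng <- if (A@p[j] < A@p[j + 1L]) (A@p[j] + 1L):A@p[j + 1L] else integer(0)
    models[[j]] <- list(annotation = modeled[[j]],
                        P = unname(counts[[modeled[[j]]]]) / n,
                        A = setNames(A@x[rng], blocks[A@i[rng] + 1L]))
  }
  names(models) <- modeled

  structure(list(models = models,
                 blocks = blocks,
                 T_n = setNames(as.numeric(T_n), blocks),
                 n_train = n,
                 min_instances = as.integer(min_instances),
                 unmodeled = sort(unmodeled),
                 backend_tag = backend_tag,
                 annotations = train$annotations),
            class = "bao_model_set")
}

incidence_matrix <- function(features, blocks) {
  i <- rep(seq_along(features), lengths(features))
  j <- match(unlist(features, use.names = FALSE), blocks)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(features), length(blocks)))
}

ann_incidence_matrix <- function(corpus, keys) {
  sets <- annotation_sets(corpus)
  sets <- lapply(sets, intersect, keys)
  i <- rep(seq_along(sets), lengths(sets))
  j <- match(unlist(sets, use.names = FALSE), keys)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(sets), length(keys)))
}

#' @export
print.bao_model_set <- function(x, ...) {
  cat(sprintf("<bao_model_set> %d models over %d blocks (n_train=%d, min_instances=%d, backend=%s); %d unmodeled\n",
              length(x$models), length(x$blocks), x$n_train,
              x$min_instances, x$backend_tag, length(x$unmodeled)))
  invisible(x)
}

#' Extract a single annotation model
#'
#' @param model_set A `bao_model_set`.
#' @param annotation Annotation key.
#' @return An `bao_annotation_model` with fields `annotation`, `P`, `A`
#'   (named non-zero counts), `T_n` (named counts over all training
#'   blocks), `n_train`, `backend_tag`.
#' @export
annotation_model <- function(model_set, annotation) {
  m <- model_set$models[[annotation]]
  if (is.null(m)) stop("no model for annotation: ", annotation)
  structure(list(annotation = m$annotation, P = m$P, A = m$A,
                 T_n = model_set$T_n, n_train = model_set$n_train,
                 backend_tag = model_set$backend_tag),
            class = "bao_annotation_model")
}

# Sparse-aware count lookup: blocks absent from the A table count 0.
sparse_counts <- function(A, block_names) {
  out <- setNames(numeric(length(block_names)), block_names)
  hit <- intersect(block_names, names(A))
  out[hit] <- A[hit]
  out
}

#' Raw Bayes score of a feature set under one annotation model
#'
#' Sums `ln((A_n+1)/(T_n*P+1))` over exactly those blocks of the feature
#' set that were seen in training; unseen blocks contribute nothing. The
#' accumulation order is descending block string, making the floating-point
#' sum reproducible.
#'
#' @param model An `bao_annotation_model` (see [annotation_model()]).
#' @param features Character vector of canonical block strings.
#' @return Raw score (unbounded real; empty sum is 0).
#' @export
raw_score <- function(model, features) {
  known <- intersect(features, names(model$T_n))
  if (!length(known)) return(0)
  known <- sort(known, decreasing = TRUE)
  A <- sparse_counts(model$A, known)
  sum(log((A + 1) / (model$T_n[known] * model$P + 1)))
}

# S[d, j] = sum over doc d's blocks of log((A+1)/(T*P+1)) for model j,
# computed in column chunks: W_chunk = log(A_chunk + 1) - log(outer(T, P) + 1).
score_matrix_chunked <- function(X, blocks, T_n, models, chunk = 200L) {
  keys <- names(models)
  S <- matrix(0, nrow(X), length(keys), dimnames = list(NULL, keys))
  for (start in seq(1L, length(keys), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(keys))
    W <- matrix(0, length(blocks), length(idx))
    for (jj in seq_along(idx)) {
      m <- models[[idx[[jj]]]]
      w <- -log(T_n * m$P + 1)
      hit <- match(names(m$A), blocks)
      w[hit] <- w[hit] + log(m$A + 1)
      W[, jj] <- w
    }
    S[, idx] <- as.matrix(X %*% W)
  }
  S
}

#' Raw scores of many documents under all models
#'
#' Vectorized scoring: returns the matrix of raw Bayes scores with one row
#' per feature set and one column per modeled annotation.
#'
#' @param model_set A `bao_model_set`.
#' @param features List of feature sets.
#' @return Numeric matrix, `length(features)` x `length(model_set$models)`.
#' @export
score_documents <- function(model_set, features) {
  blocks <- model_set$blocks
  X <- incidence_matrix(lapply(features, intersect, blocks), blocks)
  S <- score_matrix_chunked(X, blocks, model_set$T_n, model_set$models)
  rownames(S) <- names(features)
  S
}

#' Leave-one-out raw scores of training documents under all models
#'
#' Scores every training document under every model as if the document had
#' been excluded from training (counts, block inventory and prior
#' decremented exactly as a full rebuild would). Training documents score
#' their own models with a large self-count optimism when scored with the
#' full counts -- especially under sparsely trained models -- so
#' calibrations are fit on these leave-one-out scores instead.
#'
#' @param model_set A `bao_model_set` built from `train`.
#' @param train The training `bao_corpus`.
#' @param features Named list of feature sets (by `doc_id`).
#' @return Numeric matrix, documents x models.
#' @export
loo_scores <- function(model_set, train, features) {
  ids <- as.character(doc_ids(train))
  features <- features[ids]
  n <- model_set$n_train
  stopifnot(n == length(ids))
  blocks <- model_set$blocks
  X <- incidence_matrix(lapply(features, intersect, blocks), blocks)
  T_n <- model_set$T_n
  usable <- T_n > 1                # blocks seen by only one doc vanish in its fold
  keys <- names(model_set$models)
  Pm <- as.matrix(ann_incidence_matrix(train, keys)) > 0
  S <- matrix(0, n, length(keys), dimnames = list(ids, keys))
  chunk <- 200L
  for (start in seq(1L, length(keys), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(keys))
    W_pos <- matrix(0, length(blocks), length(idx))
    W_neg <- matrix(0, length(blocks), length(idx))
    for (jj in seq_along(idx)) {
      m <- model_set$models[[idx[[jj]]]]
      K <- m$P * n
      hit <- match(names(m$A), blocks)
      # negative doc: A unchanged, T loses the doc, prior K/(n-1)
      w <- -log((T_n - 1) * (K / (n - 1)) + 1)
      w[hit] <- w[hit] + log(m$A + 1)
      W_neg[, jj] <- ifelse(usable, w, 0)
      # positive doc: its blocks lose one A count and one T count
      if (K - 1 >= 1) {
        w <- -log((T_n - 1) * ((K - 1) / (n - 1)) + 1)
        w[hit] <- w[hit] + log(pmax(m$A, 1))
        W_pos[, jj] <- ifelse(usable, w, 0)
      }
    }
    S_pos <- as.matrix(X %*% W_pos)
    S_neg <- as.matrix(X %*% W_neg)
    S[, idx] <- ifelse(Pm[, idx, drop = FALSE], S_pos, S_neg)
  }
  S
}

#' Mann-Whitney AUC of a score vector against binary labels
#'
#' Area under the ROC curve computed as the pairwise-ordering statistic
#' with average ranks, so ties count one half and a constant scorer yields
#' exactly 0.5.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) ground truth.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) stop("AUC needs both positive and negative labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord]); fp <- cumsum(!labels[ord])
  # collapse score ties to a single ROC vertex
  keep <- c(diff(scores[ord]) != 0, TRUE)
  data.frame(fpr = c(0, fp[keep] / max(sum(!labels), 1L)),
             tpr = c(0, tp[keep] / max(sum(labels), 1L)))
}

#' Leave-one-out ROC for one annotation
#'
#' Scores every training document under a model rebuilt with that document
#' excluded (counts and prior decremented exactly as a full rebuild would),
#' then forms the ROC over the (score, has-annotation) pairs.
#'
#' @param train Training `bao_corpus`.
#' @param features Named list of feature sets (by `doc_id`).
#' @param annotation Annotation key.
#' @param min_instances Modelability threshold every fold must satisfy.
#' @return List with `scores`, `labels`, `roc` (data frame of fpr/tpr) and
#'   `auc`.
#' @export
loo_roc <- function(train, features, annotation, min_instances = 2L) {
  ids <- as.character(doc_ids(train))
  features <- features[ids]
  n <- length(ids)
  labels <- vapply(train$documents,
                   function(d) annotation %in% d$annotations, logical(1))
  K <- sum(labels)
  for (i in seq_len(n)) {
    if (K - labels[[i]] < min_instances)
      stop(sprintf("annotation %s falls below %d instances when document %s is held out",
                   annotation, min_instances, ids[[i]]))
  }
  blocks <- sort(unique(unlist(features, use.names = FALSE)))
  X <- incidence_matrix(features, blocks)
  T_all <- Matrix::colSums(X)
  pos <- which(labels)
  A_all <- Matrix::colSums(X[pos, , drop = FALSE])
  scores <- numeric(n)
  for (i in seq_len(n)) {
    xi <- X[i, ]
    present <- which(xi != 0)
    if (!length(present)) { scores[[i]] <- 0; next }
    T_i <- T_all[present] - 1                      # doc i excluded
    A_i <- A_all[present] - (if (labels[[i]]) 1 else 0)
    P_i <- (K - labels[[i]]) / (n - 1)
    keep <- T_i > 0                                # block unseen in the fold
    ordk <- order(blocks[present], decreasing = TRUE)
    w <- ifelse(keep, log((A_i + 1) / (T_i * P_i + 1)), 0)
    scores[[i]] <- sum(w[ordk])
  }
  list(scores = setNames(scores, ids), labels = labels,
       roc = roc_points(scores, labels),
       auc = auc_mann_whitney(scores, labels))
}
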