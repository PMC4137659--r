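# Annotation sets on real assays are highly non-orthogonal (knowing that
# an assay uses luciferin makes a luminescence readout far more likely).
# A second tier of Bayes models exploits this: for each annotation A, a
# model over the presence/absence of every *other* annotation. A document
# carrying A is an "active" example whose features are its other
# annotations; a document without A is "inactive" with all its annotations
# as features. During a session the approved set is scored under these
# models and the result, linearly calibrated and weighted, is added to the
# calibrated text score.

#' Build annotation-correlation models
#'
#' One model per annotation with at least `min_instances` training
#' occurrences, counting document-level co-occurrence with every other
#' annotation: `A_m` = documents containing both annotations, `T_m` =
#' documents containing the other annotation. An annotation never appears
#' as a feature of its own model.
#'
#' @param train Training `bao_corpus`.
#' @param min_instances Modelability threshold (default 2).
#' @return A `bao_corr_models`: named models (each with `P` and named `A`
#'   counts), the shared `T_m` table, and `n_train`.
#' @export
build_correlation_models <- function(train, min_instances = 2L) {
  if (n_documents(train) == 0L) stop("cannot build correlation models from an empty corpus")
  counts <- annotation_counts(train)
  keys <- sort(names(counts))
  modeled <- keys[counts[keys] >= min_instances]
  n <- n_documents(train)
  Y <- ann_incidence_matrix(train, keys)            # docs x all annotations
  # crossprod gives a symmetric-storage matrix; expand to general so column
  # slices carry the full co-occurrence profile
  CO <- methods::as(methods::as(Matrix::crossprod(Y), "generalMatrix"),
                    "CsparseMatrix")
  models <- lapply(modeled, function(a) {
    j <- match(a, keys)
    rng <- if (CO@p[j] < CO@p[j + 1L]) (CO@p[j] + 1L):CO@p[j + 1L] else integer(0)
    A <- setNames(CO@x[rng], keys[CO@i[rng] + 1L])
    A <- A[names(A) != a]                           # self never a feature
    list(annotation = a, P = unname(counts[[a]]) / n, A = A)
  })
  names(models) <- modeled
  structure(list(models = models,
                 T_m = setNames(as.numeric(counts[keys]), keys),
                 n_train = n,
                 min_instances = as.integer(min_instances)),
            class = "bao_corr_models")
}

#' @export
print.bao_corr_models <- function(x, ...) {
  cat(sprintf("<bao_corr_models> %d correlation models over %d annotations\n",
              length(x$models), length(x$T_m)))
  invisible(x)
}

#' Raw correlation score of an approved set under one model
#'
#' The same Laplacian-modified score equation with annotations as the
#' features: the sum over approved annotations present in the model's count
#' table of `ln((A_m+1)/(T_m*P+1))`. An empty approved set scores 0.
#'
#' @param corr A `bao_corr_models`.
#' @param annotation Annotation key whose model to apply.
#' @param approved Character vector of approved annotation keys.
#' @return Raw correlation score.
#' @export
correlation_score <- function(corr, annotation, approved) {
  m <- corr$models[[annotation]]
  if (is.null(m)) stop("no correlation model for annotation: ", annotation)
  known <- setdiff(intersect(approved, names(corr$T_m)), annotation)
  if (!length(known)) return(0)
  known <- sort(known, decreasing = TRUE)
  A <- sparse_counts(m$A, known)
  sum(log((A + 1) / (corr$T_m[known] * m$P + 1)))
}

# Weight matrix W[candidate, other]: summand contributed to candidate's
# correlation score when `other` is approved. Rows = modeled annotations;
# the candidate's own column is zeroed (never a feature of its own model).
corr_weight_matrix <- function(corr) {
  keys <- names(corr$T_m)
  W <- matrix(0, length(corr$models), length(keys),
              dimnames = list(names(corr$models), keys))
  for (a in names(corr$models)) {
    m <- corr$models[[a]]
    w <- -log(corr$T_m * m$P + 1)
    w[names(m$A)] <- w[names(m$A)] + log(m$A + 1)
    w[a] <- 0
    W[a, ] <- w
  }
  W
}

#' Calibrate correlation models on the training corpus
#'
#' Each correlation model receives the same min-max initial calibration as
#' the primary models: its training scores are the correlation scores of
#' each training document's own annotation set (minus the modeled
#' annotation itself). No iterative optimization is applied. The global
#' weight `w` scales the whole correlation term.
#'
#' @param corr A `bao_corr_models`.
#' @param train Training `bao_corpus`.
#' @param w Global correlation weight (default 1; 0 disables rescoring).
#' @return A `bao_corr_calibration`: named vectors `a`, `b` and weight `w`.
#' @export
calibrate_correlation <- function(corr, train, w = 1) {
  stopifnot(w >= 0)
  W <- corr_weight_matrix(corr)
  Y <- as.matrix(ann_incidence_matrix(train, colnames(W)))
  S <- Y %*% t(W)                                  # docs x modeled
  ab <- apply(S, 2, function(col) unlist(initial_calibration(col)))
  structure(list(a = ab["a", ], b = ab["b", ], w = w),
            class = "bao_corr_calibration")
}

#' Correlation-adjusted score
#'
#' `adjusted = calibrated + w * (a * corr_raw + b)`. Session ranking only
#' applies this once at least one annotation has been approved, so with an
#' empty approved set (or `w = 0`) the ranking is exactly the
#' calibration-only ranking.
#'
#' @param calibrated Calibrated text score(s).
#' @param corr_raw Raw correlation score(s).
#' @param a,b Per-model correlation calibration.
#' @param w Global correlation weight.
#' @return Adjusted score(s).
#' @export
adjusted_score <- function(calibrated, corr_raw, a = 1, b = 0, w = 1) {
  calibrated + w * (a * corr_raw + b)
}
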