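# Raw Bayes scores have arbitrary per-model scale, so scores from two
# models cannot be compared directly. Each model therefore carries a linear
# correction y = a*x + b (a > 0, preserving within-model order); the
# corrections are initialized by min-max normalization on the training
# scores and then optimized for the overall ability of the calibrated
# models to rank a document's present annotations above its absent ones.

#' Initial linear calibration of one model
#'
#' Maps the minimum training score to 0 and the maximum to 1. If all
#' scores are equal the fallback `a = 1, b = -min` maps everything to 0.
#'
#' @param train_scores Non-empty numeric vector of raw training scores.
#' @return List with elements `a` (> 0) and `b`.
#' @export
initial_calibration <- function(train_scores) {
  stopifnot(length(train_scores) >= 1L)
  lo <- min(train_scores); hi <- max(train_scores)
  if (hi == lo) return(list(a = 1, b = -lo))
  list(a = 1 / (hi - lo), b = -lo / (hi - lo))
}

#' Bundle a model set with per-model calibrations
#'
#' @param model_set A `bao_model_set`.
#' @param a,b Named numeric vectors (one entry per model).
#' @return A `bao_calibrated_models` object.
#' @export
calibrated_models <- function(model_set, a, b) {
  keys <- names(model_set$models)
  stopifnot(setequal(names(a), keys), setequal(names(b), keys), all(a[keys] > 0))
  structure(list(models = model_set, a = a[keys], b = b[keys]),
            class = "bao_calibrated_models")
}

#' @export
print.bao_calibrated_models <- function(x, ...) {
  cat(sprintf("<bao_calibrated_models> %d calibrated models\n", length(x$a)))
  invisible(x)
}

#' Apply the per-model calibrations to a raw-score matrix
#'
#' @param cms A `bao_calibrated_models`.
#' @param raw Matrix of raw scores (columns named by annotation key), e.g.
#'   from [score_documents()].
#' @return Matrix of calibrated scores.
#' @export
calibrate_scores <- function(cms, raw) {
  keys <- colnames(raw)
  sweep(sweep(raw, 2, cms$a[keys], `*`), 2, cms$b[keys], `+`)
}

#' Initial calibrations for every model of a set
#'
#' Min-max calibration per model over its training-score column. By
#' default the scores are computed with [score_documents()]; pass a
#' [loo_scores()] matrix to calibrate on leakage-free score ranges (what
#' [optimize_calibration()] does).
#'
#' @param model_set A `bao_model_set`.
#' @param features Named list of training feature sets.
#' @param scores Optional precomputed documents x models raw-score matrix.
#' @return A `bao_calibrated_models` with min-max initial calibrations.
#' @export
initial_calibrations <- function(model_set, features, scores = NULL) {
  raw <- if (is.null(scores)) score_documents(model_set, features) else scores
  ab <- apply(raw, 2, function(col) unlist(initial_calibration(col)))
  calibrated_models(model_set, a = ab["a", ], b = ab["b", ])
}

# --- separation objective ----------------------------------------------
#
# Internal state for the pairwise-ordering objective: S is the docs x
# models calibrated score matrix, Pm the logical present mask. For each
# document with both present and absent modeled annotations, the fraction
# of (present, absent) pairs ordered correctly is computed with ties
# counting one half; the objective is the mean over those documents.

sep_state <- function(S, Pm) {
  np <- rowSums(Pm); nn <- ncol(Pm) - np
  valid <- np > 0 & nn > 0
  C <- numeric(nrow(S))
  for (d in which(valid)) {
    r <- rank(S[d, ], ties.method = "average")
    C[[d]] <- sum(r[Pm[d, ]]) - np[[d]] * (np[[d]] + 1) / 2
  }
  list(S = S, Pm = Pm, np = np, nn = nn, valid = valid, C = C)
}

sep_value <- function(st) {
  if (!any(st$valid)) return(NA_real_)
  mean(st$C[st$valid] / (st$np[st$valid] * st$nn[st$valid]))
}

# Incremental evaluation for coordinate descent. Per valid document we
# keep the sorted present and absent score vectors; the correct-pair
# contribution of model j's score x in document d is then a pair of
# findInterval lookups (ties weighted one half), so one candidate
# evaluation costs O(docs * log models) instead of O(docs * models).

# correct pairs contributed by a present model scoring x against the
# sorted absent scores v: #(v < x) + 0.5 * #(v == x)
pairs_beaten <- function(x, v) {
  n_le <- findInterval(x, v)
  n_lt <- findInterval(x, v, left.open = TRUE)
  n_lt + 0.5 * (n_le - n_lt)
}

# correct pairs contributed by an absent model scoring x against the
# sorted present scores v: #(v > x) + 0.5 * #(v == x)
pairs_beaten_by <- function(x, v) {
  n_le <- findInterval(x, v)
  n_lt <- findInterval(x, v, left.open = TRUE)
  (length(v) - n_le) + 0.5 * (n_le - n_lt)
}

#' Ranking separation of a calibrated model set on a corpus
#'
#' For each document, every (present annotation, absent annotation) pair of
#' modeled candidates is checked: the pair counts 1 if the present
#' annotation's calibrated score is higher, 1/2 on a tie. The score is the
#' mean correct-pair fraction over documents that have both present and
#' absent modeled annotations (equivalently, the mean per-document AUC of
#' the calibrated ranking).
#'
#' @param cms A `bao_calibrated_models`.
#' @param corpus A `bao_corpus`.
#' @param features Named list of feature sets for the corpus documents.
#' @param loo Score the documents leave-one-out (only meaningful when
#'   `corpus` is the training corpus the models were built from; this is
#'   the objective [optimize_calibration()] climbs).
#' @return Fraction in `[0, 1]`.
#' @export
separation_score <- function(cms, corpus, features, loo = FALSE) {
  ids <- as.character(doc_ids(corpus))
  raw <- if (loo) loo_scores(cms$models, corpus, features)
         else score_documents(cms$models, features[ids])
  S <- calibrate_scores(cms, raw)
  Pm <- as.matrix(ann_incidence_matrix(corpus, colnames(S))) > 0
  sep_value(sep_state(S, Pm))
}

#' Optimize calibrations for global ranking separation
#'
#' Calibrations are fit and scored on leave-one-out training scores
#' ([loo_scores()]), since full-count scores of training documents carry a
#' self-count optimism that distorts both the min-max ranges and the
#' separation objective. Starting from the min-max initial calibrations,
#' performs cyclic coordinate descent: models are visited in a
#' seed-shuffled order; for each model the scale `a` is perturbed
#' multiplicatively (x 0.5, 0.8, 1.25, 2) and the offset `b` additively
#' (+/- 0.05, 0.2), and a perturbation is kept only if the global
#' separation strictly increases. Sweeps stop early when none is
#' accepted, so the result never ranks worse than the initial
#' calibrations.
#'
#' @param model_set A `bao_model_set`.
#' @param train Training `bao_corpus`.
#' @param features Named list of training feature sets.
#' @param sweeps Maximum coordinate sweeps (default 10; 0 returns the
#'   initial calibrations unchanged).
#' @param seed Integer seed controlling the model visiting order.
#' @return A `bao_calibrated_models`; the achieved separation is attached
#'   as attribute `"separation"`.
#' @export
optimize_calibration <- function(model_set, train, features, sweeps = 10L,
                                 seed = 1L) {
  stopifnot(sweeps >= 0L)
  ids <- as.character(doc_ids(train))
  raw <- loo_scores(model_set, train, features)
  cms <- initial_calibrations(model_set, features, scores = raw)
  keys <- colnames(raw)
  S <- calibrate_scores(cms, raw)
  Pm <- as.matrix(ann_incidence_matrix(train, keys)) > 0
  st <- sep_state(S, Pm)
  best <- sep_value(st)
  if (is.na(best) || sweeps == 0L) {
    attr(cms, "separation") <- best
    return(cms)
  }
  a <- cms$a; b <- cms$b
  valid <- which(st$valid)
  weight <- 1 / (st$np[valid] * st$nn[valid] * length(valid))  # per-pair weight
  # per valid document: sorted present / absent score vectors
  pres_sorted <- lapply(valid, function(d) sort(S[d, Pm[d, ]]))
  abs_sorted <- lapply(valid, function(d) sort(S[d, !Pm[d, ]]))
  # replace one value in a sorted vector (old is guaranteed to be a member)
  splice <- function(v, old, new) {
    v <- v[-findInterval(old, v)]
    append(v, new, after = findInterval(new, v))
  }
  update_sorted <- function(j, old_col, new_col) {
    for (k in seq_along(valid)) {
      d <- valid[[k]]
      if (Pm[d, j])
        pres_sorted[[k]] <<- splice(pres_sorted[[k]], old_col[[d]], new_col[[d]])
      else
        abs_sorted[[k]] <<- splice(abs_sorted[[k]], old_col[[d]], new_col[[d]])
    }
  }
  # objective contribution of model j's pairs, for several candidate score
  # columns at once (cand_S: docs x n_candidates)
  contrib_j <- function(j, cand_S) {
    total <- numeric(ncol(cand_S))
    for (k in seq_along(valid)) {
      d <- valid[[k]]
      total <- total + weight[[k]] *
        (if (Pm[d, j]) pairs_beaten(cand_S[d, ], abs_sorted[[k]])
         else pairs_beaten_by(cand_S[d, ], pres_sorted[[k]]))
    }
    total
  }
  visit_order <- with_seed(seed, sample(seq_along(keys)))
  a_steps <- c(0.5, 0.8, 1.25, 2)
  b_steps <- c(-0.2, -0.05, 0.05, 0.2)
  for (sweep_i in seq_len(sweeps)) {
    improved <- FALSE
    for (j in visit_order) {
      for (move in c("a", "b")) {
        cand_ab <- if (move == "a")
          cbind(a = a[[j]] * a_steps, b = b[[j]])
        else cbind(a = a[[j]], b = b[[j]] + b_steps)
        # column 1 = current calibration, then the candidates
        cand_S <- raw[, j] %o% c(a[[j]], cand_ab[, "a"]) +
          rep(c(b[[j]], cand_ab[, "b"]), each = nrow(raw))
        contrib <- contrib_j(j, cand_S)
        gains <- contrib[-1L] - contrib[[1L]]
        pick <- which.max(gains)
        if (gains[[pick]] > 1e-12) {
          a[[j]] <- cand_ab[pick, "a"]; b[[j]] <- cand_ab[pick, "b"]
          update_sorted(j, S[, j], cand_S[, pick + 1L])
          S[, j] <- cand_S[, pick + 1L]
          best <- best + gains[[pick]]
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  out <- calibrated_models(model_set, a, b)
  attr(out, "separation") <- best
  out
}

# Run code under a temporary RNG state; restores the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
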