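# Versioned, self-describing flat-file serialization of a trained model
# bundle (primary Bayes models + calibrations + correlation models +
# annotation labels). Counts are stored, not log-ratios, so P and every
# score summand are exactly recomputable from the file. Numbers are
# written with 17 significant digits, giving bit-exact round-trips of
# doubles.

MODEL_FORMAT <- "baoannotator-models"
MODEL_VERSION <- 1L

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a trained model bundle to a flat file
#'
#' Tab-separated records: a header (format, version, n_train,
#' min_instances, backend identity, correlation weight), the shared block
#' table with `T_n` counts, per-model priors, calibrations and `A_n`
#' counts, correlation models, and annotation label records.
#'
#' @param path Output file.
#' @param cms A `bao_calibrated_models`.
#' @param corr A `bao_corr_models`, or `NULL`.
#' @param corr_cal A `bao_corr_calibration`, or `NULL`.
#' @return Invisibly, `path`.
#' @export
write_model_file <- function(path, cms, corr = NULL, corr_cal = NULL) {
  ms <- cms$models
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., sep = "\t"), con)
  w("format", MODEL_FORMAT)
  w("version", MODEL_VERSION)
  w("n_train", ms$n_train)
  w("min_instances", ms$min_instances)
  w("backend", ms$backend_tag)
  w("corr_weight", fmt_num(if (is.null(corr_cal)) 0 else corr_cal$w))
  for (i in seq_along(ms$blocks))
    w("block", i, ms$blocks[[i]], fmt_num(ms$T_n[[i]]))
  for (key in names(ms$models)) {
    m <- ms$models[[key]]
    w("model", key, fmt_num(m$P), fmt_num(cms$a[[key]]), fmt_num(cms$b[[key]]))
    idx <- match(names(m$A), ms$blocks)
    for (i in seq_along(m$A))
      w("count", key, idx[[i]], fmt_num(m$A[[i]]))
  }
  for (key in ms$unmodeled) w("unmodeled", key)
  if (!is.null(corr)) {
    for (key in names(corr$T_m))
      w("annT", key, fmt_num(corr$T_m[[key]]))
    for (key in names(corr$models)) {
      m <- corr$models[[key]]
      ca <- if (is.null(corr_cal)) 1 else corr_cal$a[[key]]
      cb <- if (is.null(corr_cal)) 0 else corr_cal$b[[key]]
      w("corrmodel", key, fmt_num(m$P), fmt_num(ca), fmt_num(cb))
      nz <- which(m$A > 0)
      for (o in names(m$A)[nz]) w("corrcount", key, o, fmt_num(m$A[[o]]))
    }
  }
  tab <- ms$annotations
  if (!is.null(tab) && nrow(tab)) {
    clean <- function(x) gsub("[\t\r\n]", " ", x)
    for (i in seq_len(nrow(tab)))
      w("label", tab$key[[i]], clean(tab$property_label[[i]]),
        clean(tab$value_label[[i]]))
  }
  invisible(path)
}

#' Read a model bundle written by [write_model_file()]
#'
#' The backend identity recorded in the file is checked against
#' `expect_backend`; a mismatch is an error, because features extracted by
#' a different tagging backend are not comparable with the trained counts.
#'
#' @param path Model file.
#' @param expect_backend Expected NLP backend tag (default the package's
#'   own backend); `NULL` skips the check.
#' @return List with elements `cms` (a `bao_calibrated_models`), `corr`
#'   (a `bao_corr_models` or `NULL`) and `corr_cal`.
#' @export
read_model_file <- function(path, expect_backend = nlp_backend_tag()) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  recs <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(recs, `[[`, "", 1L)
  get1 <- function(k) {
    i <- which(kind == k)
    if (!length(i)) stop("model file missing '", k, "' record")
    recs[[i[[1]]]][[2]]
  }
  if (!identical(get1("format"), MODEL_FORMAT))
    stop("not a ", MODEL_FORMAT, " file: ", path)
  if (as.integer(get1("version")) > MODEL_VERSION)
    stop("model file version ", get1("version"), " is newer than supported")
  backend <- get1("backend")
  if (!is.null(expect_backend) && !identical(backend, expect_backend))
    stop("model file was built with NLP backend '", backend,
         "', but this package provides '", expect_backend, "'")
  n_train <- as.integer(get1("n_train"))
  min_instances <- as.integer(get1("min_instances"))
  corr_w <- as.numeric(get1("corr_weight"))

  brec <- recs[kind == "block"]
  blocks <- vapply(brec, `[[`, "", 3L)
  ord <- order(as.integer(vapply(brec, `[[`, "", 2L)))
  blocks <- blocks[ord]
  T_n <- setNames(as.numeric(vapply(brec, `[[`, "", 4L))[ord], blocks)

  mrec <- recs[kind == "model"]
  crec <- recs[kind == "count"]
  count_key <- vapply(crec, `[[`, "", 2L)
  models <- list(); a <- numeric(0); b <- numeric(0)
  for (r in mrec) {
    key <- r[[2]]
    mine <- crec[count_key == key]
    A <- if (length(mine)) {
      idx <- as.integer(vapply(mine, `[[`, "", 3L))
      setNames(as.numeric(vapply(mine, `[[`, "", 4L)), blocks[idx])
    } else setNames(numeric(0), character(0))
    models[[key]] <- list(annotation = key, P = as.numeric(r[[3]]), A = A)
    a[[key]] <- as.numeric(r[[4]])
    b[[key]] <- as.numeric(r[[5]])
  }
  unmodeled <- vapply(recs[kind == "unmodeled"], `[[`, "", 2L)

  lrec <- recs[kind == "label"]
  tab <- ann_unkey(vapply(lrec, `[[`, "", 2L))
  tab$property_label <- vapply(lrec, function(r) if (length(r) >= 3) r[[3]] else "", "")
  tab$value_label <- vapply(lrec, function(r) if (length(r) >= 4) r[[4]] else "", "")

  ms <- structure(list(models = models, blocks = blocks, T_n = T_n,
                       n_train = n_train, min_instances = min_instances,
                       unmodeled = sort(unmodeled), backend_tag = backend,
                       annotations = tab),
                  class = "bao_model_set")
  cms <- calibrated_models(ms, a, b)

  corr <- NULL; corr_cal <- NULL
  trec <- recs[kind == "annT"]
  if (length(trec)) {
    T_m <- setNames(as.numeric(vapply(trec, `[[`, "", 3L)),
                    vapply(trec, `[[`, "", 2L))
    T_m <- T_m[sort(names(T_m))]
    cmrec <- recs[kind == "corrmodel"]
    ccrec <- recs[kind == "corrcount"]
    cc_key <- vapply(ccrec, `[[`, "", 2L)
    cmodels <- list(); ca <- numeric(0); cb <- numeric(0)
    for (r in cmrec) {
      key <- r[[2]]
      mine <- ccrec[cc_key == key]
      A <- if (length(mine)) {
        setNames(as.numeric(vapply(mine, `[[`, "", 4L)),
                 vapply(mine, `[[`, "", 3L))
      } else setNames(numeric(0), character(0))
      cmodels[[key]] <- list(annotation = key, P = as.numeric(r[[3]]), A = A)
      ca[[key]] <- as.numeric(r[[4]])
      cb[[key]] <- as.numeric(r[[5]])
    }
    corr <- structure(list(models = cmodels, T_m = T_m, n_train = n_train,
                           min_instances = min_instances),
                      class = "bao_corr_models")
    corr_cal <- structure(list(a = ca, b = cb, w = corr_w),
                          class = "bao_corr_calibration")
  }
  list(cms = cms, corr = corr, corr_cal = corr_cal)
}

#' Train a full model bundle from a corpus
#'
#' Convenience pipeline: feature extraction, Bayes model building,
#' calibration optimization, correlation models and their calibration.
#'
#' @param train Training `bao_corpus`.
#' @param min_instances Modelability threshold.
#' @param max_tokens Feature block size limit.
#' @param sweeps Calibration optimization sweeps.
#' @param w Correlation weight.
#' @param seed Seed for the calibration visiting order.
#' @param features Precomputed feature sets (optional).
#' @return List with `cms`, `corr`, `corr_cal`, `features`.
#' @export
train_models <- function(train, min_instances = 2L, max_tokens = 8L,
                         sweeps = 10L, w = 1, seed = 1L, features = NULL) {
  if (is.null(features)) features <- corpus_features(train, max_tokens)
  ms <- build_models(train, features, min_instances)
  cms <- optimize_calibration(ms, train, features, sweeps = sweeps, seed = seed)
  corr <- build_correlation_models(train, min_instances)
  corr_cal <- calibrate_correlation(corr, train, w = w)
  list(cms = cms, corr = corr, corr_cal = corr_cal, features = features)
}
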