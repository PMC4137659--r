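# Annotations are identified by the pair (property URI, value URI); labels
# are carried alongside but never enter equality. Internally an annotation
# is addressed by a single key string "propertyURI valueURI" (URIs contain
# no spaces).

#' Build / split annotation keys
#'
#' An annotation is the pair (property URI, value URI); equality is defined
#' on the URIs only. `ann_key()` forms the canonical key string and
#' `ann_unkey()` recovers the URI pair(s).
#'
#' @param property_uri,value_uri Character vectors of ontology URIs.
#' @param key Character vector of keys produced by `ann_key()`.
#' @return `ann_key()`: character vector of keys. `ann_unkey()`: data frame
#'   with columns `key`, `property_uri`, `value_uri`.
#' @export
ann_key <- function(property_uri, value_uri) {
  stopifnot(all(nzchar(property_uri)), all(nzchar(value_uri)))
  paste(property_uri, value_uri)
}

#' @rdname ann_key
#' @export
ann_unkey <- function(key) {
  sp <- regexpr(" ", key, fixed = TRUE)
  data.frame(key = key,
             property_uri = substring(key, 1L, sp - 1L),
             value_uri = substring(key, sp + 1L),
             stringsAsFactors = FALSE)
}

#' Construct a document
#'
#' @param doc_id External assay identifier (positive integer, e.g. PubChem AID).
#' @param text Plain protocol text.
#' @param annotations Character vector of annotation keys (deduplicated).
#' @return A `bao_document` list.
#' @export
new_document <- function(doc_id, text = "", annotations = character()) {
  structure(list(doc_id = as.integer(doc_id),
                 text = as.character(text),
                 annotations = sort(unique(as.character(annotations)))),
            class = "bao_document")
}

#' Construct a corpus
#'
#' A corpus is an ordered list of documents plus the annotation universe
#' (every distinct property:value pair present, with labels) and a
#' URI -> label index.
#'
#' @param documents List of `bao_document` objects with unique `doc_id`s.
#' @param annotations Optional data frame describing the universe, with
#'   columns `key`, `property_uri`, `value_uri`, `property_label`,
#'   `value_label`. Rows for keys absent from the documents are dropped;
#'   missing keys get empty labels.
#' @param labels Named character vector, URI -> human-readable label.
#' @return A `bao_corpus` object.
#' @export
new_corpus <- function(documents = list(), annotations = NULL,
                       labels = character()) {
  ids <- vapply(documents, function(d) d$doc_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate doc_id in corpus: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  universe <- sort(unique(unlist(lapply(documents, `[[`, "annotations"))))
  tab <- ann_unkey(universe)
  tab$property_label <- unname(ifelse(tab$property_uri %in% names(labels),
                                      labels[tab$property_uri], ""))
  tab$value_label <- unname(ifelse(tab$value_uri %in% names(labels),
                                   labels[tab$value_uri], ""))
  if (!is.null(annotations) && nrow(annotations)) {
    m <- match(tab$key, annotations$key)
    hit <- !is.na(m)
    if ("property_label" %in% names(annotations))
      tab$property_label[hit] <- annotations$property_label[m[hit]]
    if ("value_label" %in% names(annotations))
      tab$value_label[hit] <- annotations$value_label[m[hit]]
  }
  structure(list(documents = documents[order(ids)],
                 annotations = tab,
                 labels = labels),
            class = "bao_corpus")
}

#' @export
print.bao_corpus <- function(x, ...) {
  cat(sprintf("<bao_corpus> %d documents, %d distinct annotations\n",
              length(x$documents), nrow(x$annotations)))
  invisible(x)
}

#' Number of documents in a corpus
#' @param corpus A `bao_corpus`.
#' @return Integer count.
#' @export
n_documents <- function(corpus) length(corpus$documents)

doc_ids <- function(corpus) vapply(corpus$documents, `[[`, integer(1), "doc_id")

annotation_sets <- function(corpus) lapply(corpus$documents, `[[`, "annotations")

# Count, for every annotation key, the number of documents carrying it.
annotation_counts <- function(corpus) {
  anns <- unlist(annotation_sets(corpus), use.names = FALSE)
  if (!length(anns)) return(integer(0))
  tab <- table(anns)
  setNames(as.integer(tab), names(tab))
}

#' Annotation frequency in a corpus
#'
#' The fraction of documents carrying an annotation; this is the score the
#' frequency-ranking null baseline assigns (an annotation in 100 of 698
#' documents scores 0.143).
#'
#' @param corpus A `bao_corpus`.
#' @param annotation An annotation key (`ann_key()`).
#' @return Fraction in `[0, 1]`.
#' @export
annotation_frequency <- function(corpus, annotation) {
  n <- n_documents(corpus)
  if (n == 0L) stop("annotation_frequency is undefined for an empty corpus")
  hits <- sum(vapply(corpus$documents,
                     function(d) annotation %in% d$annotations, logical(1)))
  hits / n
}

#' Remove documents with duplicate annotation sets
#'
#' Among documents sharing an identical set of property:value annotations,
#' only the one with the smallest `doc_id` is retained (documents may still
#' differ in free text, which is not part of the training signal).
#'
#' @param corpus A `bao_corpus`.
#' @return List with elements `corpus` (deduplicated) and `removed_count`.
#' @export
deduplicate <- function(corpus) {
  ids <- doc_ids(corpus)
  sig <- vapply(corpus$documents,
                function(d) paste(d$annotations, collapse = "\r"), "")
  ord <- order(ids)                       # keep smallest doc_id per group
  keep_idx <- ord[!duplicated(sig[ord])]
  keep_idx <- sort(keep_idx)
  out <- new_corpus(corpus$documents[keep_idx], corpus$annotations, corpus$labels)
  list(corpus = out, removed_count = length(corpus$documents) - length(keep_idx))
}

#' Partition a corpus into training and test sets
#'
#' Greedy deterministic selection: documents are visited in ascending
#' `doc_id`; a document is admitted to the test set iff (i) every one of its
#' annotations currently has more than `min_train_instances` occurrences
#' among documents not yet admitted to the test set, and (ii) none of its
#' annotations already occurs in the test set. This guarantees that every
#' annotation of every test document retains at least `min_train_instances`
#' training occurrences and that each annotation occurs in at most one test
#' document.
#'
#' @param corpus A deduplicated `bao_corpus`.
#' @param min_train_instances Minimum training occurrences to preserve
#'   (default 2).
#' @return List with `bao_corpus` elements `train` and `test`.
#' @export
partition_corpus <- function(corpus, min_train_instances = 2L) {
  stopifnot(min_train_instances >= 1L)
  counts <- annotation_counts(corpus)      # occurrences among non-test docs
  in_test <- character(0)                  # annotations already in the test set
  ids <- doc_ids(corpus)
  ord <- order(ids)
  test_idx <- integer(0)
  for (i in ord) {
    anns <- corpus$documents[[i]]$annotations
    if (!length(anns)) next
    if (any(anns %in% in_test)) next
    if (all(counts[anns] > min_train_instances)) {
      test_idx <- c(test_idx, i)
      counts[anns] <- counts[anns] - 1L
      in_test <- c(in_test, anns)
    }
  }
  train_idx <- setdiff(seq_along(corpus$documents), test_idx)
  list(train = new_corpus(corpus$documents[train_idx], corpus$annotations, corpus$labels),
       test = new_corpus(corpus$documents[test_idx], corpus$annotations, corpus$labels))
}

#' Read a URI -> label table
#'
#' @param path Two-column tab-separated file: URI, label.
#' @return Named character vector.
#' @export
read_label_table <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    quote = "", col.names = c("uri", "label"))
  setNames(tab$label, tab$uri)
}

#' Load an annotated assay corpus
#'
#' Two dialects are accepted:
#' \describe{
#'   \item{`"ttl"`}{A Turtle file of triples: per assay, one subject URI
#'     with one triple per property:value annotation (both URIs), a
#'     `cdd:PubChemAID` integer literal binding the assay identifier, and a
#'     `cdd:hasDescription` string literal carrying the curated text.
#'     `rdfs:label` triples populate the label index. Annotation triples
#'     whose value is a string literal are dropped (only URI-valued
#'     annotations are retained); records with malformed URIs are skipped
#'     with a warning and counted.}
#'   \item{`"simple"`}{A tab-separated file of
#'     \code{assayID<TAB>propertyURI<TAB>valueURI} rows, plus a sidecar
#'     directory of per-assay `<assayID>.txt` text files.}
#' }
#'
#' @param path Corpus file path.
#' @param format `"ttl"` or `"simple"`.
#' @param text_dir Directory of `<doc_id>.txt` files (simple dialect).
#' @param labels Optional URI -> label vector merged into the corpus index.
#' @return A `bao_corpus`; the number of skipped malformed records is
#'   attached as attribute `"skipped"`.
#' @export
load_corpus <- function(path, format = c("ttl", "simple"), text_dir = NULL,
                        labels = character()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (format == "ttl") load_corpus_ttl(path, labels) else
    load_corpus_simple(path, text_dir, labels)
}

uri_ok <- function(x) grepl("^[A-Za-z][A-Za-z0-9+.-]*://?[^[:space:]]+$", x) |
  grepl("^urn:[^[:space:]]+$", x)

TEXT_PRED <- function() paste0(CDD_NS, "hasDescription")
AID_PRED  <- function() paste0(CDD_NS, "PubChemAID")
LABEL_PRED <- function() paste0(RDFS_NS, "label")

load_corpus_ttl <- function(path, labels = character()) {
  g <- read_turtle(path)
  skipped <- 0L
  lbl_rows <- g$predicate == LABEL_PRED() & g$object_type == "string"
  file_labels <- setNames(g$object[lbl_rows], g$subject[lbl_rows])
  labels <- c(labels, file_labels[setdiff(names(file_labels), names(labels))])
  g <- g[!lbl_rows, , drop = FALSE]

  aid_rows <- g$predicate == AID_PRED()
  aid_by_subj <- setNames(suppressWarnings(as.integer(g$object[aid_rows])),
                          g$subject[aid_rows])
  docs <- list()
  for (subj in names(aid_by_subj)) {
    rows <- g[g$subject == subj, , drop = FALSE]
    text_i <- rows$predicate == TEXT_PRED() & rows$object_type == "string"
    text <- if (any(text_i)) rows$object[text_i][[1]] else ""
    ann_i <- rows$object_type == "uri" & rows$predicate != AID_PRED() &
      rows$predicate != TEXT_PRED()
    ann_rows <- rows[ann_i, , drop = FALSE]
    bad <- !uri_ok(ann_rows$predicate) | !uri_ok(ann_rows$object)
    if (any(bad)) {
      skipped <- skipped + sum(bad)
      ann_rows <- ann_rows[!bad, , drop = FALSE]
    }
    # string-literal annotation values are intentionally not training data
    anns <- if (nrow(ann_rows)) ann_key(ann_rows$predicate, ann_rows$object) else character(0)
    docs[[length(docs) + 1L]] <- new_document(aid_by_subj[[subj]], text, anns)
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d annotation triple(s) with malformed URIs", skipped))
  out <- new_corpus(docs, labels = labels)
  attr(out, "skipped") <- skipped
  out
}

load_corpus_simple <- function(path, text_dir = NULL, labels = character()) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  skipped <- 0L
  recs <- strsplit(raw, "\t", fixed = TRUE)
  docs_ann <- list()
  for (r in recs) {
    if (length(r) != 3L || is.na(suppressWarnings(as.integer(r[[1]]))) ||
        !uri_ok(r[[2]]) || !uri_ok(r[[3]])) {
      skipped <- skipped + 1L
      next
    }
    id <- r[[1]]
    docs_ann[[id]] <- c(docs_ann[[id]], ann_key(r[[2]], r[[3]]))
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d malformed record(s)", skipped))
  docs <- lapply(names(docs_ann), function(id) {
    text <- ""
    if (!is.null(text_dir)) {
      f <- file.path(text_dir, paste0(id, ".txt"))
      if (file.exists(f))
        text <- paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
    }
    new_document(as.integer(id), text, docs_ann[[id]])
  })
  out <- new_corpus(docs, labels = labels)
  attr(out, "skipped") <- skipped
  out
}

#' Write a corpus in an exchange dialect
#'
#' The simple dialect writes `triples.tsv` (assayID, property URI, value URI)
#' plus a `texts/` directory of per-document `.txt` files, and `labels.tsv`
#' when the corpus carries labels. The ttl dialect writes one Turtle file
#' with annotation triples, `cdd:PubChemAID`, `cdd:hasDescription` and
#' `rdfs:label` triples. Both round-trip through [load_corpus()].
#'
#' @param corpus A `bao_corpus`.
#' @param path Output directory (simple) or `.ttl` file path (ttl).
#' @param format `"simple"` or `"ttl"`.
#' @return Invisibly, the main file path written.
#' @export
write_corpus <- function(corpus, path, format = c("simple", "ttl")) {
  format <- match.arg(format)
  if (format == "simple") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(path, "texts"), showWarnings = FALSE)
    rows <- do.call(rbind, lapply(corpus$documents, function(d) {
      if (!length(d$annotations)) return(NULL)
      cbind(d$doc_id, ann_unkey(d$annotations)[, c("property_uri", "value_uri")])
    }))
    tf <- file.path(path, "triples.tsv")
    if (is.null(rows)) {
      file.create(tf)
    } else {
      write.table(rows, tf, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
    for (d in corpus$documents)
      writeLines(d$text, file.path(path, "texts", paste0(d$doc_id, ".txt")))
    if (length(corpus$labels))
      write.table(data.frame(names(corpus$labels), unname(corpus$labels)),
                  file.path(path, "labels.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    return(invisible(tf))
  }
  g <- corpus_to_graph(corpus)
  write_turtle(g, path)
  invisible(path)
}

corpus_to_graph <- function(corpus) {
  parts <- lapply(corpus$documents, function(d) {
    subj <- paste0(CDD_NS, "aid", d$doc_id)
    g <- rdf_graph(subj, AID_PRED(), as.character(d$doc_id), "integer")
    if (nzchar(d$text))
      g <- rdf_bind(g, rdf_graph(subj, TEXT_PRED(), d$text, "string"))
    if (length(d$annotations)) {
      u <- ann_unkey(d$annotations)
      g <- rdf_bind(g, rdf_graph(subj, u$property_uri, u$value_uri, "uri"))
    }
    g
  })
  g <- do.call(rdf_bind, c(parts, list(label_triples(corpus$labels))))
  rdf_canonicalize(g)
}

#' Reload a corpus written by [write_corpus()]
#'
#' @param path Directory (simple) or `.ttl` file.
#' @param format Dialect.
#' @return A `bao_corpus`.
#' @export
read_corpus_fixture <- function(path, format = c("simple", "ttl")) {
  format <- match.arg(format)
  if (format == "simple") {
    lab_file <- file.path(path, "labels.tsv")
    labels <- if (file.exists(lab_file)) read_label_table(lab_file) else character()
    corp <- load_corpus(file.path(path, "triples.tsv"), "simple",
                        text_dir = file.path(path, "texts"), labels = labels)
    # documents with text but no annotations are not in triples.tsv
    seen <- doc_ids(corp)
    txts <- list.files(file.path(path, "texts"), pattern = "\\.txt$")
    extra_ids <- setdiff(as.integer(sub("\\.txt$", "", txts)), seen)
    if (length(extra_ids)) {
      extra <- lapply(extra_ids, function(id) {
        text <- paste(readLines(file.path(path, "texts", paste0(id, ".txt")),
                                warn = FALSE), collapse = "\n")
        new_document(id, text)
      })
      corp <- new_corpus(c(corp$documents, extra), corp$annotations, corp$labels)
    }
    return(corp)
  }
  load_corpus(path, "ttl")
}
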