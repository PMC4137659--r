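# Namespaces used throughout the bioassay annotation exchange format.
BAO_NS  <- "http://www.bioassayontology.org/bao#"
CDD_NS  <- "http://www.collaborativedrug.com/bao/curation.owl#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"

#' Default namespace prefixes for Turtle output
#'
#' @return Named character vector mapping prefix to namespace URI.
#' @export
default_prefixes <- function() {
  c(bao = BAO_NS, cdd = CDD_NS, rdfs = RDFS_NS, xsd = XSD_NS)
}

#' Construct an RDF graph from its components
#'
#' An RDF graph is represented as a data frame with columns `subject`,
#' `predicate`, `object` and `object_type` (one of `"uri"`, `"string"`,
#' `"integer"`). Subjects and predicates are always URIs.
#'
#' @param subject,predicate,object Character vectors (recycled).
#' @param object_type Character vector of object kinds.
#' @return An `rdf_graph` data frame.
#' @export
rdf_graph <- function(subject = character(), predicate = character(),
                      object = character(), object_type = character()) {
  n <- max(length(subject), length(predicate), length(object))
  recycle <- function(x) if (length(x) == 1L && n > 1L) rep(x, n) else x
  subject <- recycle(subject); predicate <- recycle(predicate)
  object <- recycle(object); object_type <- recycle(object_type)
  stopifnot(length(subject) == length(predicate),
            length(subject) == length(object),
            length(object_type) == length(subject))
  bad <- !object_type %in% c("uri", "string", "integer")
  if (any(bad)) stop("unknown object_type: ", paste(unique(object_type[bad]), collapse = ", "))
  g <- data.frame(subject = as.character(subject),
                  predicate = as.character(predicate),
                  object = as.character(object),
                  object_type = as.character(object_type),
                  stringsAsFactors = FALSE)
  class(g) <- c("rdf_graph", "data.frame")
  g
}

rdf_bind <- function(...) {
  parts <- list(...)
  g <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)))
  class(g) <- c("rdf_graph", "data.frame")
  g
}

# Drop exact duplicate triples; order rows deterministically.
rdf_canonicalize <- function(graph) {
  key <- paste(graph$subject, graph$predicate, graph$object, graph$object_type, sep = "\r")
  graph <- graph[!duplicated(key), , drop = FALSE]
  ord <- order(graph$subject, graph$predicate, graph$object_type, graph$object)
  graph <- graph[ord, , drop = FALSE]
  rownames(graph) <- NULL
  class(graph) <- c("rdf_graph", "data.frame")
  graph
}

#' Set equality of two ground RDF graphs
#'
#' Graphs emitted by this package contain no blank nodes, so graph
#' isomorphism reduces to triple-set equality.
#'
#' @param g1,g2 `rdf_graph` objects.
#' @return Logical scalar.
#' @export
rdf_equal <- function(g1, g2) {
  k <- function(g) sort(paste(g$subject, g$predicate, g$object, g$object_type, sep = "\r"))
  identical(k(rdf_canonicalize(g1)), k(rdf_canonicalize(g2)))
}

uri_compact <- function(uri, prefixes) {
  for (p in names(prefixes)) {
    ns <- prefixes[[p]]
    if (startsWith(uri, ns)) {
      local <- substring(uri, nchar(ns) + 1L)
      # only compact when the local part is a safe prefixed-name token
      if (grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", local) && !endsWith(local, "."))
        return(paste0(p, ":", local))
    }
  }
  paste0("<", uri, ">")
}

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

ttl_unescape <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    buf <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      ch <- chars[[j]]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[[j + 1L]]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t", "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        buf <- c(buf, ch)
        j <- j + 1L
      }
    }
    out[[i]] <- paste(buf, collapse = "")
  }
  out
}

format_object <- function(object, object_type, prefixes) {
  switch(object_type,
         uri = uri_compact(object, prefixes),
         string = paste0("\"", ttl_escape(object), "\""),
         integer = object,
         stop("unknown object_type: ", object_type))
}

#' Serialize an RDF graph as Turtle
#'
#' Output is deterministic: prefix declarations first, then triples sorted by
#' subject, predicate and object, grouped per subject with `;` continuation.
#'
#' @param graph An `rdf_graph`.
#' @param path Output file path, or `NULL` to return the text.
#' @param prefixes Named character vector of prefix -> namespace mappings.
#' @return Invisibly, the Turtle text (a character vector of lines).
#' @export
write_turtle <- function(graph, path = NULL, prefixes = default_prefixes()) {
  graph <- rdf_canonicalize(graph)
  lines <- sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes))
  lines <- c(lines, "")
  for (subj in unique(graph$subject)) {
    rows <- graph[graph$subject == subj, , drop = FALSE]
    head <- uri_compact(subj, prefixes)
    body <- sprintf("    %s %s",
                    vapply(rows$predicate, uri_compact, "", prefixes = prefixes),
                    mapply(format_object, rows$object, rows$object_type,
                           MoreArgs = list(prefixes = prefixes)))
    sep <- c(rep(" ;", nrow(rows) - 1L), " .")
    lines <- c(lines, head, paste0(body, sep), "")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# Tokenize a Turtle document into a character vector of lexical tokens.
ttl_tokenize <- function(text) {
  s <- paste(text, collapse = "\n")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (ch %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (ch == "#") {             # comment to end of line
      while (i <= n && chars[[i]] != "\n") i <- i + 1L
      next
    }
    if (ch == "<") {             # IRIREF
      j <- i + 1L
      while (j <= n && chars[[j]] != ">") j <- j + 1L
      if (j > n) stop("unterminated IRI in Turtle input")
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
      next
    }
    if (ch == "\"") {            # string literal
      j <- i + 1L
      buf <- "\""
      while (j <= n) {
        cj <- chars[[j]]
        if (cj == "\\") { buf <- paste0(buf, cj, chars[[j + 1L]]); j <- j + 2L; next }
        buf <- paste0(buf, cj)
        if (cj == "\"") break
        j <- j + 1L
      }
      if (j > n) stop("unterminated string literal in Turtle input")
      # optional ^^datatype
      i <- j + 1L
      if (i + 1L <= n && chars[[i]] == "^" && chars[[i + 1L]] == "^") {
        k <- i + 2L
        if (chars[[k]] == "<") {
          m <- k
          while (m <= n && chars[[m]] != ">") m <- m + 1L
          buf <- paste0(buf, "^^", paste(chars[k:m], collapse = ""))
          i <- m + 1L
        } else {
          m <- k
          while (m <= n && !chars[[m]] %in% c(" ", "\t", "\n", "\r", ";", ",", ".")) m <- m + 1L
          buf <- paste0(buf, "^^", paste(chars[k:(m - 1L)], collapse = ""))
          i <- m
        }
      }
      tokens <- c(tokens, buf)
      next
    }
    if (ch %in% c(".", ";", ",")) {
      # '.' can also start a decimal, but this dialect has no leading-dot numbers
      tokens <- c(tokens, ch)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !chars[[j]] %in% c(" ", "\t", "\n", "\r", ";", ",", "<", "\"", "#")) {
      if (chars[[j]] == "." && (j == n || chars[[j + 1L]] %in% c(" ", "\t", "\n", "\r"))) break
      j <- j + 1L
    }
    tokens <- c(tokens, paste(chars[i:(j - 1L)], collapse = ""))
    i <- j
  }
  tokens
}

resolve_term <- function(token, prefixes) {
  if (startsWith(token, "<")) {
    return(list(value = substring(token, 2L, nchar(token) - 1L), type = "uri"))
  }
  if (startsWith(token, "\"")) {
    m <- regmatches(token, regexec('^"(.*)"(\\^\\^(.+))?$', token))[[1]]
    lit <- ttl_unescape(m[[2]])
    dt <- m[[4]]
    if (nzchar(dt)) {
      dt_uri <- resolve_term(dt, prefixes)$value
      if (identical(dt_uri, paste0(XSD_NS, "integer")) || identical(dt_uri, paste0(XSD_NS, "int")))
        return(list(value = lit, type = "integer"))
    }
    return(list(value = lit, type = "string"))
  }
  if (grepl("^[+-]?[0-9]+$", token)) return(list(value = token, type = "integer"))
  if (token == "a") return(list(value = "http://www.w3.org/1999/02/22-rdf-syntax-ns#type", type = "uri"))
  colon <- regexpr(":", token, fixed = TRUE)
  if (colon > 0L) {
    p <- substring(token, 1L, colon - 1L)
    local <- substring(token, colon + 1L)
    if (!p %in% names(prefixes)) stop("undeclared prefix '", p, ":' in Turtle input")
    return(list(value = paste0(prefixes[[p]], local), type = "uri"))
  }
  stop("cannot interpret Turtle term: ", token)
}

#' Parse a Turtle document
#'
#' Supports the dialect this package emits: `@prefix` declarations, URI and
#' prefixed-name terms, plain and integer-typed literals, and `;` / `,`
#' continuation. Blank nodes and collections are not supported.
#'
#' @param path Path to a `.ttl` file, or `text =` a character vector.
#' @param text Turtle source text (alternative to `path`).
#' @return An `rdf_graph`.
#' @export
read_turtle <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- readLines(path, warn = FALSE, encoding = "UTF-8")
  tokens <- ttl_tokenize(text)
  prefixes <- character(0)
  subj <- pred <- character(0)
  out_s <- out_p <- out_o <- out_t <- character(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    tok <- tokens[[i]]
    if (tok %in% c("@prefix", "PREFIX")) {
      pfx <- sub(":$", "", tokens[[i + 1L]])
      iri <- tokens[[i + 2L]]
      prefixes[[pfx]] <- substring(iri, 2L, nchar(iri) - 1L)
      i <- i + 3L
      if (i <= n && tokens[[i]] == ".") i <- i + 1L
      next
    }
    subj <- resolve_term(tok, prefixes)$value
    i <- i + 1L
    repeat {
      pred <- resolve_term(tokens[[i]], prefixes)$value
      i <- i + 1L
      repeat {
        obj <- resolve_term(tokens[[i]], prefixes)
        out_s <- c(out_s, subj); out_p <- c(out_p, pred)
        out_o <- c(out_o, obj$value); out_t <- c(out_t, obj$type)
        i <- i + 1L
        if (i <= n && tokens[[i]] == ",") { i <- i + 1L; next }
        break
      }
      if (i <= n && tokens[[i]] == ";") {
        i <- i + 1L
        if (i <= n && tokens[[i]] == ".") { i <- i + 1L; break }  # trailing ;.
        next
      }
      if (i <= n && tokens[[i]] == ".") { i <- i + 1L }
      break
    }
  }
  rdf_graph(out_s, out_p, out_o, out_t)
}

#' Express an annotated document as RDF triples
#'
#' Emits one triple per approved property:value annotation (subject is the
#' document URI, predicate the property URI, object the value URI), a
#' `cdd:PubChemAID` integer triple binding the assay identifier, and one
#' plain-literal triple per free-text annotation.
#'
#' @param doc_id Assay identifier (positive integer, e.g. a PubChem AID).
#' @param approved Data frame with columns `property_uri`, `value_uri`
#'   (e.g. the approved rows of a session), or a character vector of
#'   annotation keys.
#' @param free_text Optional data frame with columns `property_uri`, `text`.
#' @param base_uri Namespace for minting the document URI; the document URI
#'   is `paste0(base_uri, "aid", doc_id)`.
#' @return An `rdf_graph`.
#' @export
to_triples <- function(doc_id, approved = NULL, free_text = NULL,
                       base_uri = CDD_NS) {
  doc_uri <- paste0(base_uri, "aid", doc_id)
  g <- rdf_graph(doc_uri, paste0(CDD_NS, "PubChemAID"),
                 as.character(as.integer(doc_id)), "integer")
  if (!is.null(approved)) {
    if (is.character(approved)) approved <- ann_unkey(approved)
    if (nrow(approved))
      g <- rdf_bind(g, rdf_graph(doc_uri, approved$property_uri,
                                 approved$value_uri, "uri"))
  }
  if (!is.null(free_text) && NROW(free_text))
    g <- rdf_bind(g, rdf_graph(doc_uri, free_text$property_uri,
                               free_text$text, "string"))
  rdf_canonicalize(g)
}

#' Label triples for an rdf_graph
#'
#' Builds `rdfs:label` triples from a URI -> label map so that label-based
#' queries (joins through `rdfs:label`) can run against the in-memory graph.
#'
#' @param labels Named character vector, names are URIs.
#' @return An `rdf_graph` of `rdfs:label` triples.
#' @export
label_triples <- function(labels) {
  labels <- labels[nzchar(labels)]
  rdf_graph(names(labels), paste0(RDFS_NS, "label"), unname(labels), "string")
}

#' Conjunctive triple-pattern query
#'
#' Matches a basic graph pattern (a conjunction of triple patterns, variables
#' written `?name`) against a graph by exhaustive join, in the spirit of a
#' SPARQL SELECT over ground triples. No transitive-closure or OWL reasoning
#' is performed.
#'
#' @param graph An `rdf_graph`.
#' @param patterns List of length-3 character vectors (subject, predicate,
#'   object); terms beginning with `?` are variables, everything else is a
#'   constant (URIs given in full, literals as plain strings).
#' @param select Character vector of variable names (without `?`) to return.
#' @return A data frame with one column per selected variable, sorted by the
#'   select variables.
#' @export
query_triples <- function(graph, patterns, select) {
  stopifnot(is.list(patterns), length(select) >= 1L)
  vars_seen <- character(0)
  for (p in patterns) {
    stopifnot(length(p) == 3L)
    if (!any(startsWith(p, "?")) && !any(p %in% graph$object)) {
      # fully ground pattern: fine, acts as an existence filter
    }
    vars_seen <- union(vars_seen, sub("^\\?", "", p[startsWith(p, "?")]))
  }
  missing_sel <- setdiff(select, vars_seen)
  if (length(missing_sel))
    stop("select variable(s) not bound by any pattern: ",
         paste(missing_sel, collapse = ", "))

  cols <- list(graph$subject, graph$predicate, graph$object)
  bindings <- data.frame(row.names = 1L)  # one empty binding
  for (p in patterns) {
    keep <- rep(TRUE, nrow(graph))
    pat_vars <- character(3)
    for (k in 1:3) {
      if (startsWith(p[[k]], "?")) pat_vars[[k]] <- sub("^\\?", "", p[[k]])
      else keep <- keep & cols[[k]] == p[[k]]
    }
    matched <- data.frame(row.names = seq_len(sum(keep)))
    for (k in 1:3) {
      if (nzchar(pat_vars[[k]])) matched[[pat_vars[[k]]]] <- cols[[k]][keep]
    }
    # drop duplicate-variable contradictions (e.g. ?x ?p ?x)
    dup <- pat_vars[nzchar(pat_vars)][duplicated(pat_vars[nzchar(pat_vars)])]
    join_vars <- intersect(names(matched), names(bindings))
    if (length(join_vars)) {
      bindings <- merge(bindings, unique(matched), by = join_vars)
    } else {
      if (nrow(matched) == 0L) return(empty_bindings(select))
      matched <- unique(matched)
      if (ncol(matched) == 0L) next       # ground pattern satisfied
      bindings <- if (ncol(bindings) == 0L) matched
                  else merge(bindings, matched, by = NULL)  # cross join
    }
    if (nrow(bindings) == 0L) return(empty_bindings(select))
  }
  out <- unique(bindings[, select, drop = FALSE])
  out <- out[do.call(order, out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_bindings <- function(select) {
  out <- as.data.frame(setNames(rep(list(character(0)), length(select)), select))
  out
}

#' Read a triple-pattern query file
#'
#' One pattern per line: three whitespace-separated terms; `?name` marks a
#' variable; `<uri>` or `prefix:local` (with `@prefix` lines declaring
#' prefixes) denote URIs; double-quoted terms are string literals. Blank
#' lines and `#` comments are ignored.
#'
#' @param path File path.
#' @param prefixes Additional prefix map merged over [default_prefixes()].
#' @return List of length-3 character vectors.
#' @export
read_patterns <- function(path, prefixes = default_prefixes()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pats <- list()
  for (ln in lines) {
    if (startsWith(ln, "@prefix")) {
      toks <- ttl_tokenize(ln)
      pfx <- sub(":$", "", toks[[2]])
      prefixes[[pfx]] <- substring(toks[[3]], 2L, nchar(toks[[3]]) - 1L)
      next
    }
    toks <- ttl_tokenize(ln)
    toks <- toks[toks != "."]
    if (length(toks) != 3L) stop("pattern line must have three terms: ", ln)
    terms <- vapply(toks, function(tk) {
      if (startsWith(tk, "?")) tk else resolve_term(tk, prefixes)$value
    }, "")
    pats[[length(pats) + 1L]] <- unname(terms)
  }
  pats
}
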