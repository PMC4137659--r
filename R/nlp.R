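# Part-of-speech tagging and phrase chunking. The backend is a compact
# deterministic rule-based English tagger (closed-class lexicon + suffix
# heuristics) with an NP/PP/VP chunker. Models record the backend identity
# so that training and application always use the same feature dialect.

NLP_BACKEND <- "baoannotator-rulechunk/1"

#' Identity string of the POS tagging / chunking backend
#'
#' Stored inside saved model files and checked at load, so that features
#' extracted at prediction time are guaranteed to come from the same
#' dialect the models were trained on.
#'
#' @return Character scalar.
#' @export
nlp_backend_tag <- function() NLP_BACKEND

# --- POS tree -----------------------------------------------------------

#' Construct part-of-speech tree nodes
#'
#' A `pos_tree` is either a leaf (a tagged word token) or an internal node
#' (a phrase tag over an ordered list of child trees).
#'
#' @param tag POS tag (leaf) or phrase tag (node), e.g. `"NN"`, `"NP"`.
#' @param token Word text (leaf only, non-empty).
#' @param children List of `pos_tree` children (node only, non-empty).
#' @return A `pos_tree`.
#' @export
pos_leaf <- function(tag, token) {
  stopifnot(nzchar(tag), nzchar(token))
  structure(list(label = tag, children = list(), token = token),
            class = "pos_tree")
}

#' @rdname pos_leaf
#' @export
pos_node <- function(tag, children) {
  stopifnot(nzchar(tag), length(children) >= 1L)
  structure(list(label = tag, children = children, token = ""),
            class = "pos_tree")
}

is_leaf <- function(tree) length(tree$children) == 0L

#' Leaf tokens of a pos_tree, in order
#' @param tree A `pos_tree`.
#' @return Character vector of word tokens.
#' @export
tree_tokens <- function(tree) {
  if (is_leaf(tree)) return(tree$token)
  unlist(lapply(tree$children, tree_tokens), use.names = FALSE)
}

n_leaves <- function(tree) {
  if (is_leaf(tree)) return(1L)
  sum(vapply(tree$children, n_leaves, integer(1)))
}

#' Canonical string form of a POS block
#'
#' Serializes a subtree in parenthesized `(TAG child ...)` notation with
#' single spaces; leaf tokens are case-folded so that surface-casing
#' variants hit the same feature. Two structurally equal trees always
#' produce identical strings.
#'
#' @param tree A `pos_tree`.
#' @return Character scalar.
#' @export
canonical_block <- function(tree) {
  if (is_leaf(tree))
    return(paste0("(", tree$label, " ", tolower(tree$token), ")"))
  inner <- vapply(tree$children, canonical_block, "")
  paste0("(", tree$label, " ", paste(inner, collapse = " "), ")")
}

#' @export
print.pos_tree <- function(x, ...) {
  cat(canonical_block(x), "\n")
  invisible(x)
}

# --- tagging ------------------------------------------------------------

CLOSED_CLASS <- c(
  the = "DT", a = "DT", an = "DT", this = "DT", that = "DT", these = "DT",
  those = "DT", each = "DT", any = "DT", all = "DT", no = "DT", some = "DT",
  of = "IN", "in" = "IN", with = "IN", "for" = "IN", by = "IN", to = "IN",
  on = "IN", at = "IN", from = "IN", into = "IN", onto = "IN", as = "IN",
  under = "IN", over = "IN", between = "IN", within = "IN", without = "IN",
  after = "IN", before = "IN", during = "IN", against = "IN", per = "IN",
  via = "IN", upon = "IN",
  and = "CC", or = "CC", but = "CC", nor = "CC",
  it = "PRP", they = "PRP", we = "PRP", its = "PRP$", their = "PRP$",
  can = "MD", may = "MD", will = "MD", must = "MD", should = "MD",
  could = "MD", would = "MD",
  is = "VBZ", are = "VBP", was = "VBD", were = "VBD", be = "VB",
  been = "VBN", being = "VBG", has = "VBZ", have = "VBP", had = "VBD",
  does = "VBZ", "do" = "VBP", did = "VBD", uses = "VBZ", use = "VBP",
  contains = "VBZ", contain = "VBP", measures = "VBZ", measure = "VBP",
  not = "RB", then = "RB", also = "RB", when = "WRB", where = "WRB",
  how = "WRB", why = "WRB", which = "WDT", what = "WDT", who = "WP"
)

tag_word <- function(word, sentence_initial = FALSE) {
  lw <- tolower(word)
  if (lw %in% names(CLOSED_CLASS)) return(unname(CLOSED_CLASS[[lw]]))
  if (grepl("^[0-9]+([.,][0-9]+)*%?$", word)) return("CD")
  if (grepl("-", word, fixed = TRUE)) return("JJ")  # e.g. anti-cancer, dose-dependent
  if (grepl("[A-Z]", substring(word, 1L, 1L)) && !sentence_initial &&
      grepl("[a-z]", word)) return("NNP")
  if (grepl("[A-Z].*[A-Z0-9]", word)) return("NNP")           # acronyms, IDs
  if (nchar(lw) > 4L && endsWith(lw, "ing")) return("VBG")
  if (nchar(lw) > 3L && endsWith(lw, "ed")) return("VBN")
  if (nchar(lw) > 3L && endsWith(lw, "ly")) return("RB")
  if (grepl("(ous|ic|ive|al|ar|ary|like|dependent|based|free)$", lw) &&
      nchar(lw) > 4L) return("JJ")
  if (nchar(lw) > 3L && grepl("[^su]s$", lw)) return("NNS")
  "NN"
}

split_sentences <- function(text) {
  text <- gsub("[\r\n]+", " ", text)
  s <- unlist(strsplit(text, "(?<=[.!?])\\s+", perl = TRUE), use.names = FALSE)
  s <- trimws(s)
  s[nzchar(s)]
}

tokenize_sentence <- function(sentence) {
  # keep internal hyphens and slashes; strip other punctuation
  cleaned <- gsub("[^A-Za-z0-9/%'-]", " ", sentence)
  toks <- unlist(strsplit(cleaned, "\\s+"), use.names = FALSE)
  toks <- gsub("^[-/']+|[-/']+$", "", toks)
  toks[nzchar(toks)]
}

# --- chunking -----------------------------------------------------------

# Group a tagged token sequence into NP / PP / VP chunks; a single NP+PP
# sequence is nested as (NP (NP ...) (PP ...)) so that multi-level blocks
# of the kind "(NP (NP incubation) (PP (IN with) (NP test compound)))"
# arise. Tokens not absorbed by a chunk stay as bare leaves under S.
chunk_sentence <- function(tokens, tags) {
  n <- length(tokens)
  leaves <- mapply(pos_leaf, tags, tokens, SIMPLIFY = FALSE)
  chunks <- list()
  i <- 1L
  noun_tags <- c("NN", "NNS", "NNP", "CD")
  verb_tags <- c("VB", "VBZ", "VBP", "VBD", "VBG", "VBN", "MD")
  take_np <- function(i) {
    j <- i
    if (j <= n && tags[[j]] == "DT") j <- j + 1L
    while (j <= n && tags[[j]] %in% c("JJ", "RB")) j <- j + 1L
    k <- j
    while (k <= n && tags[[k]] %in% noun_tags) k <- k + 1L
    if (k == j) return(NULL)                 # no noun head
    span <- i:(k - 1L)
    list(node = if (length(span) == 1L) leaves[[span]]
         else pos_node("NP", leaves[span]), next_i = k)
  }
  while (i <= n) {
    tg <- tags[[i]]
    if (tg == "IN" && i < n) {
      np <- take_np(i + 1L)
      if (!is.null(np)) {
        chunks[[length(chunks) + 1L]] <-
          pos_node("PP", list(leaves[[i]], np$node))
        i <- np$next_i
        next
      }
    }
    if (tg %in% verb_tags) {
      j <- i
      while (j <= n && tags[[j]] %in% verb_tags) j <- j + 1L
      vp_children <- leaves[i:(j - 1L)]
      np <- if (j <= n) take_np(j) else NULL
      if (!is.null(np)) {
        vp_children <- c(vp_children, list(np$node))
        j <- np$next_i
      }
      chunks[[length(chunks) + 1L]] <-
        if (length(vp_children) == 1L) vp_children[[1L]]
        else pos_node("VP", vp_children)
      i <- j
      next
    }
    np <- take_np(i)
    if (!is.null(np)) {
      chunks[[length(chunks) + 1L]] <- np$node
      i <- np$next_i
      next
    }
    chunks[[length(chunks) + 1L]] <- leaves[[i]]
    i <- i + 1L
  }
  # attach a PP following an NP: (NP (NP ...) (PP ...))
  merged <- list()
  k <- 1L
  while (k <= length(chunks)) {
    cur <- chunks[[k]]
    if (!is_leaf(cur) && cur$label == "NP" && k < length(chunks)) {
      nxt <- chunks[[k + 1L]]
      if (!is_leaf(nxt) && nxt$label == "PP") {
        merged[[length(merged) + 1L]] <- pos_node("NP", list(cur, nxt))
        k <- k + 2L
        next
      }
    }
    merged[[length(merged) + 1L]] <- cur
    k <- k + 1L
  }
  if (length(merged) == 1L) merged[[1L]] else pos_node("S", merged)
}

#' Parse text into part-of-speech chunk trees
#'
#' Splits the text into sentences, tags each word, and groups the tagged
#' tokens into noun/prepositional/verb phrase chunks. The leaves of each
#' tree, concatenated, reproduce the sentence's word tokens.
#'
#' @param text Plain text (empty text yields an empty list).
#' @return List of `pos_tree`, one per sentence.
#' @export
parse_text <- function(text) {
  sentences <- split_sentences(text)
  out <- list()
  for (s in sentences) {
    toks <- tokenize_sentence(s)
    if (!length(toks)) next
    tags <- character(length(toks))
    for (k in seq_along(toks)) tags[[k]] <- tag_word(toks[[k]], sentence_initial = (k == 1L))
    out[[length(out) + 1L]] <- chunk_sentence(toks, tags)
  }
  out
}

all_subtrees <- function(tree) {
  subs <- list(tree)
  for (ch in tree$children) subs <- c(subs, all_subtrees(ch))
  subs
}

#' Extract the POS-block feature set of parsed text
#'
#' Collects the canonical string of every subtree (at every depth, single
#' leaves included) spanning at most `max_tokens` word tokens, over all
#' sentence trees. Set semantics: a block occurring many times in one
#' document counts once.
#'
#' @param trees List of `pos_tree` (from [parse_text()]).
#' @param max_tokens Block size limit in word tokens (default 8).
#' @return Sorted character vector of canonical block strings.
#' @export
extract_blocks <- function(trees, max_tokens = 8L) {
  stopifnot(max_tokens >= 1L)
  blocks <- character(0)
  for (tr in trees) {
    for (sub in all_subtrees(tr)) {
      if (n_leaves(sub) <= max_tokens)
        blocks <- c(blocks, canonical_block(sub))
    }
  }
  sort(unique(blocks))
}

#' Feature set of a plain-text document
#'
#' Convenience wrapper: `extract_blocks(parse_text(text), max_tokens)`.
#'
#' @param text Plain text.
#' @param max_tokens Block size limit.
#' @return Sorted character vector of canonical block strings.
#' @export
text_features <- function(text, max_tokens = 8L) {
  extract_blocks(parse_text(text), max_tokens)
}

#' Feature sets for every document of a corpus
#'
#' @param corpus A `bao_corpus`.
#' @param max_tokens Block size limit.
#' @return Named list (by `doc_id`) of feature sets.
#' @export
corpus_features <- function(corpus, max_tokens = 8L) {
  out <- lapply(corpus$documents, function(d) text_features(d$text, max_tokens))
  names(out) <- as.character(doc_ids(corpus))
  out
}
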