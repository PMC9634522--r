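# Pre-parsed sentence records: ingestion and alignment to entity offsets.
#
# The sidecar schema is a CoNLL-style tab-separated record, one token per
# line, sentences separated by blank lines:
#
#   <index>\t<form>\t<pos>\t<head>\t<deprel>\t<char_start>\t<char_end>
#
# `index` is 1-based within the sentence, `head` 0 denotes the syntactic
# root, and character offsets are 0-based half-open over the raw document
# text (the same convention as the .a1 files). Comment lines start with '#'.

#' Parse a dependency-parse sidecar
#'
#' @param content sidecar file content (single string); see the schema above.
#' @return list of sentence graphs; each a `sentence_graph` list with
#'   `tokens` (data.frame `form`, `pos`, `start`, `end`), `edges`
#'   (data.frame `head`, `dep`, `deprel`, 1-based token indices, root rows
#'   omitted), and document character offsets `start`, `end`.
#' @export
read_parses <- function(content) {
  lines <- strsplit(content, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^#", lines)]
  groups <- split(lines, cumsum(!nzchar(trimws(lines))))
  sentences <- list()
  for (g in groups) {
    g <- g[nzchar(trimws(g))]
    if (!length(g)) next
    fields <- do.call(rbind, strsplit(g, "\t", fixed = TRUE))
    if (ncol(fields) != 7L)
      stopf("parse sidecar: expected 7 tab-separated fields, got %d in '%s'",
            ncol(fields), g[1])
    idx <- as.integer(fields[, 1])
    if (!identical(idx, seq_along(idx)))
      stopf("parse sidecar: token indices must run 1..n within a sentence")
    tokens <- data.frame(form = fields[, 2], pos = fields[, 3],
                         start = as.integer(fields[, 6]),
                         end = as.integer(fields[, 7]))
    heads <- as.integer(fields[, 4])
    if (any(heads < 0L | heads > nrow(tokens)))
      stopf("parse sidecar: head index out of range")
    keep <- heads != 0L
    edges <- data.frame(head = heads[keep], dep = idx[keep],
                        deprel = fields[keep, 5])
    sentences[[length(sentences) + 1L]] <- sentence_graph(tokens, edges)
  }
  sentences
}

#' Construct a sentence graph
#'
#' @param tokens data.frame with columns `form`, `pos`, `start`, `end`
#'   (0-based half-open character offsets, strictly increasing and
#'   non-overlapping).
#' @param edges data.frame with columns `head`, `dep`, `deprel` (1-based
#'   token indices).
#' @return a `sentence_graph`.
#' @export
sentence_graph <- function(tokens, edges) {
  n <- nrow(tokens)
  if (n == 0L) stopf("sentence with no tokens")
  if (any(tokens$start >= tokens$end))
    stopf("sentence token with empty span")
  if (n > 1L && any(tokens$start[-1] < tokens$end[-n]))
    stopf("sentence token offsets overlap or are out of order")
  if (nrow(edges) && any(edges$head < 1L | edges$head > n | edges$dep < 1L | edges$dep > n))
    stopf("dependency edge endpoint out of token range 1..%d", n)
  structure(
    list(tokens = tokens, edges = edges,
         start = min(tokens$start), end = max(tokens$end)),
    class = "sentence_graph"
  )
}

#' @export
print.sentence_graph <- function(x, ...) {
  cat(sprintf("<sentence_graph: %d tokens, %d edges, chars [%d,%d)>\n",
              nrow(x$tokens), nrow(x$edges), x$start, x$end))
  invisible(x)
}

format_parses <- function(sentences, doc_id) {
  out <- c(sprintf("# doc_id = %s", doc_id))
  for (s in sentences) {
    heads <- rep(0L, nrow(s$tokens))
    deprels <- rep("root", nrow(s$tokens))
    if (nrow(s$edges)) {
      heads[s$edges$dep] <- s$edges$head
      deprels[s$edges$dep] <- s$edges$deprel
    }
    out <- c(out, sprintf("%d\t%s\t%s\t%d\t%s\t%d\t%d",
                          seq_len(nrow(s$tokens)), s$tokens$form, s$tokens$pos,
                          heads, deprels, s$tokens$start, s$tokens$end),
             "")
  }
  paste0(out, collapse = "\n")
}

#' Attach sentence parses to a document
#'
#' Aligns pre-parsed sentences to a document and resolves each entity to a
#' token span by character overlap: a token belongs to an entity's span when
#' their character intervals intersect, which is robust to tokenizer/entity
#' boundary mismatches (e.g. the tokens `N.` and `gonorrhoeae` both overlap
#' the entity `N. gonorrhoeae`). Entities whose overlapping tokens fall in
#' more than one sentence (or in none) are flagged `cross_sentence` and
#' yield no candidate instances downstream. Token forms are verified against
#' the document text; 1-based offsets are detected and rejected.
#'
#' @param doc a `biorel_document`.
#' @param parse_records list of `sentence_graph` (from [read_parses()]), in
#'   document order.
#' @return the document with `sentences` populated and entity `token_span` /
#'   `sentence` / `cross_sentence` fields filled.
#' @export
attach_parses <- function(doc, parse_records) {
  for (s in parse_records) {
    for (i in seq_len(nrow(s$tokens))) {
      tok <- s$tokens[i, ]
      got <- slice(doc$text, tok$start, tok$end)
      if (got != tok$form) {
        shifted <- slice(doc$text, tok$start - 1L, tok$end - 1L)
        if (identical(shifted, tok$form))
          stopf("doc %s: token '%s' matches at offsets shifted by -1; parse records look 1-based, but 0-based half-open offsets are required",
                doc$doc_id, tok$form)
        stopf("doc %s: token '%s' does not match text slice '%s' at [%d,%d)",
              doc$doc_id, tok$form, got, tok$start, tok$end)
      }
    }
  }
  starts <- vapply(parse_records, `[[`, numeric(1), "start")
  if (is.unsorted(starts)) stopf("doc %s: parse sentences out of order", doc$doc_id)
  doc$sentences <- parse_records
  for (id in names(doc$entities)) {
    e <- doc$entities[[id]]
    hits <- list()
    for (si in seq_along(parse_records)) {
      tok <- parse_records[[si]]$tokens
      ov <- which(tok$start < e$end & tok$end > e$start)
      if (length(ov)) hits[[length(hits) + 1L]] <- list(sent = si, span = range(ov))
    }
    if (length(hits) == 1L) {
      e$sentence <- hits[[1]]$sent
      e$token_span <- hits[[1]]$span
      e$cross_sentence <- FALSE
    } else {
      if (length(hits) == 0L)
        warnf("doc %s: entity %s overlaps no parsed token; flagged cross-sentence",
              doc$doc_id, id)
      e$sentence <- NA_integer_
      e$token_span <- NULL
      e$cross_sentence <- TRUE
    }
    doc$entities[[id]] <- e
  }
  doc
}
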