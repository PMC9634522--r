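# Candidate instance construction.
#
# Only positive pairs are annotated in the gold corpora, so classification
# instances are built by enumerating every unordered intrasentence entity
# pair whose type pair is legal under the task constraints; pairs without a
# gold annotation become "none" (non-relation) instances. Intersentence gold
# relations are ignored, and pairs with no dependency path between their
# head tokens are dropped before modeling.

#' Enumerate candidate instances for a document
#'
#' One instance per unordered intrasentence entity pair whose type pair
#' occurs in at least one legal (type, type, category) triple. Gold-annotated
#' pairs carry their category (one instance per gold category when a pair is
#' annotated with several); all other legal pairs are labeled `"none"`.
#' A gold annotation whose category is illegal for the pair's types is kept
#' with a warning — the corpus is trusted over the rules. Self pairs and
#' identical-offset duplicate entities are skipped.
#'
#' Each instance carries the per-token entity-type sequence (the two
#' candidate entities' types, all other tokens "non-entity"), the two signed
#' token-distance sequences, and the oriented shortest dependency path
#' between the entity head tokens (`NULL` when disconnected; see
#' [filter_no_path()]).
#'
#' @param doc a `biorel_document` with parses attached.
#' @param rules a [task_config()].
#' @param head_rule entity head-token rule, see [entity_head_token()].
#' @return list of `candidate_instance` records.
#' @export
enumerate_candidates <- function(doc, rules, head_rule = "last") {
  if (!length(doc$sentences))
    stopf("doc %s: no sentences attached; call attach_parses() first", doc$doc_id)
  gold_key <- character(0)
  gold_cat <- character(0)
  if (nrow(doc$relations)) {
    gold_key <- pair_key(doc$relations$arg1, doc$relations$arg2)
    gold_cat <- doc$relations$rtype
  }
  out <- list()
  for (si in seq_along(doc$sentences)) {
    sent <- doc$sentences[[si]]
    ents <- Filter(function(e) !e$cross_sentence && identical(e$sentence, si),
                   doc$entities)
    if (length(ents) < 2L) next
    ord <- order(vapply(ents, function(e) e$token_span[1], numeric(1)),
                 vapply(ents, function(e) e$token_span[2], numeric(1)))
    ents <- ents[ord]
    graph <- build_undirected_graph(sent)
    for (i in seq_len(length(ents) - 1L)) {
      for (j in seq((i + 1L), length(ents))) {
        e1 <- ents[[i]]; e2 <- ents[[j]]
        if (e1$start == e2$start && e1$end == e2$end) next
        legal <- legal_categories(rules, e1$etype, e2$etype)
        hit <- which(gold_key == pair_key(e1$id, e2$id))
        labels <- unique(gold_cat[hit])
        if (length(labels) == 0L) {
          if (length(legal) == 0L) next
          labels <- "none"
        } else {
          bad <- setdiff(labels, legal)
          if (length(bad))
            warnf("doc %s: pair (%s,%s) annotated %s though types (%s,%s) do not license it; keeping gold label",
                  doc$doc_id, e1$id, e2$id, paste(bad, collapse = "/"),
                  e1$etype, e2$etype)
        }
        for (lab in labels) {
          out[[length(out) + 1L]] <-
            build_instance(doc$doc_id, si, sent, graph, e1, e2, lab,
                           rules, head_rule)
        }
      }
    }
  }
  out
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

build_instance <- function(doc_id, si, sent, graph, e1, e2, label, rules, head_rule) {
  n <- nrow(sent$tokens)
  etype_seq <- rep(NA_character_, n)
  etype_seq[seq(e1$token_span[1], e1$token_span[2])] <- e1$etype
  etype_seq[seq(e2$token_span[1], e2$token_span[2])] <- e2$etype
  h1 <- entity_head_token(e1, head_rule)
  h2 <- entity_head_token(e2, head_rule)
  sdp <- NULL
  if (h1 != h2) {
    raw <- shortest_dependency_path(graph, h1, h2)
    if (!is.null(raw)) {
      sdp <- orient_path(raw, e1, e2, rules)
      sdp$words <- sent$tokens$form[sdp$token_idx]
      sdp <- unclass(sdp)[c("token_idx", "words", "deptype_seq", "m")]
    }
  }
  structure(
    list(doc_id = doc_id, sentence = si,
         e1_id = e1$id, e2_id = e2$id,
         e1_type = e1$etype, e2_type = e2$etype,
         tokens = sent$tokens$form, pos = sent$tokens$pos,
         label = label,
         entity_type_seq = etype_seq,
         dist1_seq = token_distances(n, e1$token_span),
         dist2_seq = token_distances(n, e2$token_span),
         sdp = sdp, intra = TRUE),
    class = "candidate_instance"
  )
}

# Signed distance from every token to the nearest token of an entity span:
# 0 inside the span, negative before it, positive after it.
token_distances <- function(n, span) {
  idx <- seq_len(n)
  ifelse(idx < span[1], idx - span[1],
         ifelse(idx > span[2], idx - span[2], 0L))
}

#' @export
print.candidate_instance <- function(x, ...) {
  cat(sprintf("<candidate_instance %s s%d (%s,%s) %s: n=%d m=%s>\n",
              x$doc_id, x$sentence, x$e1_id, x$e2_id, x$label,
              length(x$tokens), if (is.null(x$sdp)) "NA" else x$sdp$m))
  invisible(x)
}

#' Drop instances without a dependency path
#'
#' Removes candidate instances whose entity head tokens lie in disconnected
#' components of the sentence's dependency graph, reporting the removal
#' count.
#'
#' @param instances list of `candidate_instance`.
#' @param quiet suppress the removal-count message.
#' @return the filtered instance list.
#' @export
filter_no_path <- function(instances, quiet = FALSE) {
  keep <- vapply(instances, function(x) !is.null(x$sdp), logical(1))
  if (!quiet && any(!keep))
    message(sprintf("filter_no_path: removed %d of %d instances with no dependency path",
                    sum(!keep), length(keep)))
  instances[keep]
}

#' Subsample negative instances
#'
#' Training corpora are dominated by enumerated non-relation pairs; a fixed
#' fraction is kept, deleting `floor((1 - keep_fraction) * N_neg)` negatives
#' uniformly at random. Positives are always kept, so the positive count is
#' invariant. Deterministic given `seed`. Validation and test splits should
#' not be subsampled.
#'
#' @param instances list of `candidate_instance`.
#' @param keep_fraction fraction of negatives to keep, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return the subsampled instance list (original order preserved).
#' @export
subsample_negatives <- function(instances, keep_fraction, seed) {
  if (!is.numeric(keep_fraction) || keep_fraction < 0 || keep_fraction > 1)
    stopf("keep_fraction must be in [0, 1], got %s", format(keep_fraction))
  neg <- which(vapply(instances, function(x) x$label == "none", logical(1)))
  n_delete <- floor((1 - keep_fraction) * length(neg))
  if (n_delete == 0L) return(instances)
  drop <- withr::with_seed(seed, sample(neg, n_delete))
  instances[-drop]
}

#' Per-category instance counts
#'
#' @param instances list of `candidate_instance`.
#' @return list with `counts` (named integer vector per category, including
#'   `none`), `positives`, `negatives` and `total`; `total` always equals
#'   the sum of the per-category counts.
#' @export
corpus_statistics <- function(instances) {
  labels <- vapply(instances, `[[`, character(1), "label")
  counts <- if (length(labels)) table(labels) else table(character())
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts,
       positives = sum(counts[names(counts) != "none"]),
       negatives = sum(counts[names(counts) == "none"]),
       total = sum(counts))
}

#' Dump and load candidate instances as JSON-lines
#'
#' @param instances list of `candidate_instance`.
#' @param path output file.
#' @export
write_instances_jsonl <- function(instances, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (x in instances) {
    writeLines(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, null = "null",
                                na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_instances_jsonl
#' @export
read_instances_jsonl <- function(path) {
  lapply(readLines(path, warn = FALSE), function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    x$entity_type_seq <- as.character(x$entity_type_seq)
    if (!is.null(x$sdp)) x$sdp <- lapply(x$sdp, unlist)
    structure(x, class = "candidate_instance")
  })
}
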