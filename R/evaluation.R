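# Micro-averaged relation-extraction evaluation.
#
# A prediction is correct iff its (document, unordered entity pair,
# category) triple matches a gold relation — strict matching. Scores are
# reported as percentages with per-category rows, a pooled (micro) aggregate
# and an intrasentence sub-report. Gold intersentence relations count as
# false negatives for an intrasentence-only system, which is why
# intrasentence F1 exceeds the overall F1.

#' Harmonic F1 from precision and recall
#'
#' `F1 = 2PR / (P + R)`, 0 when `P + R = 0`. Works on either the 0-1 or the
#' percentage scale.
#'
#' @param precision,recall numeric.
#' @return F1 on the same scale.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
       f1 = f1_score(p, r))
}

rel_keys <- function(rel) {
  paste(rel$doc_id, pmin(rel$e1, rel$e2), pmax(rel$e1, rel$e2), rel$rtype,
        sep = "\r")
}

#' Score predicted relations against gold
#'
#' @param predicted data.frame with columns `doc_id`, `e1`, `e2`, `rtype`
#'   (`"none"` rows are ignored; duplicate keys are collapsed with a
#'   warning).
#' @param gold data.frame with the same columns plus optionally `intra`
#'   (logical: both entities in one sentence; assumed `TRUE` when absent).
#' @return an `eval_report`: `overall` (micro-pooled tp/fp/fn and percentage
#'   precision/recall/F1), `by_category` (one row each), and `intra` (the
#'   same computed against intrasentence gold only).
#' @export
score <- function(predicted, gold) {
  predicted <- predicted[predicted$rtype != "none", , drop = FALSE]
  gold <- gold[gold$rtype != "none", , drop = FALSE]
  pk <- rel_keys(predicted)
  if (anyDuplicated(pk)) {
    warnf("collapsed %d duplicate predicted relation(s)", sum(duplicated(pk)))
    predicted <- predicted[!duplicated(pk), , drop = FALSE]
  }
  gk <- rel_keys(gold)
  if (anyDuplicated(gk)) gold <- gold[!duplicated(gk), , drop = FALSE]
  if (is.null(gold$intra)) gold$intra <- TRUE
  rep <- list(
    overall = pooled_counts(predicted, gold),
    by_category = category_table(predicted, gold),
    intra = pooled_counts(predicted, gold[gold$intra, , drop = FALSE]),
    intra_by_category = category_table(predicted, gold[gold$intra, , drop = FALSE])
  )
  structure(rep, class = "eval_report")
}

pooled_counts <- function(predicted, gold) {
  pk <- rel_keys(predicted); gk <- rel_keys(gold)
  tp <- sum(pk %in% gk)
  prf(tp, length(pk) - tp, length(gk) - tp)
}

category_table <- function(predicted, gold) {
  cats <- sort(unique(c(predicted$rtype, gold$rtype)))
  rows <- lapply(cats, function(cc) {
    x <- pooled_counts(predicted[predicted$rtype == cc, , drop = FALSE],
                       gold[gold$rtype == cc, , drop = FALSE])
    data.frame(category = cc, tp = x$tp, fp = x$fp, fn = x$fn,
               precision = x$precision, recall = x$recall, f1 = x$f1)
  })
  if (!length(rows)) {
    return(data.frame(category = character(), tp = integer(), fp = integer(),
                      fn = integer(), precision = numeric(),
                      recall = numeric(), f1 = numeric()))
  }
  do.call(rbind, rows)
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(z) sprintf("P %.2f R %.2f F1 %.2f (tp %d fp %d fn %d)",
                             round_half_up(z$precision), round_half_up(z$recall),
                             round_half_up(z$f1), z$tp, z$fp, z$fn)
  cat("Overall:       ", fmt(x$overall), "\n")
  cat("Intrasentence: ", fmt(x$intra), "\n")
  if (nrow(x$by_category)) {
    for (i in seq_len(nrow(x$by_category))) {
      r <- x$by_category[i, ]
      cat(sprintf("  %-28s P %6.2f R %6.2f F1 %6.2f\n", r$category,
                  round_half_up(r$precision), round_half_up(r$recall),
                  round_half_up(r$f1)))
    }
  }
  invisible(x)
}

#' Pool an evaluation report into category clusters
#'
#' Counts are pooled within each cluster, then precision/recall/F1 are
#' computed per cluster. Total true positives are conserved across clusters.
#'
#' @param report an [score()] result.
#' @param mapping named character vector `category -> cluster`, or the path
#'   of a YAML file mapping cluster names to category lists (the shipped
#'   `seedev_clusters.yaml` layout).
#' @return data.frame with one row per cluster (`cluster`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`).
#' @export
cluster_report <- function(report, mapping) {
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping)) {
    y <- yaml::read_yaml(mapping)
    mapping <- stats::setNames(rep(names(y), lengths(y)), unlist(y))
  }
  bc <- report$by_category
  unmapped <- setdiff(bc$category, names(mapping))
  if (length(unmapped))
    stopf("cluster mapping misses categor%s: %s",
          if (length(unmapped) > 1) "ies" else "y",
          paste(unmapped, collapse = ", "))
  cl <- unname(mapping[bc$category])
  rows <- lapply(unique(cl), function(cc) {
    sub <- bc[cl == cc, , drop = FALSE]
    x <- prf(sum(sub$tp), sum(sub$fp), sum(sub$fn))
    data.frame(cluster = cc, tp = x$tp, fp = x$fp, fn = x$fn,
               precision = x$precision, recall = x$recall, f1 = x$f1)
  })
  do.call(rbind, rows)
}

#' Collect gold relations from documents
#'
#' @param docs list of `biorel_document` (with parses attached, so the
#'   intrasentence flag can be computed).
#' @return data.frame `doc_id`, `e1`, `e2`, `rtype`, `intra`.
#' @export
gold_relations <- function(docs) {
  rows <- lapply(docs, function(doc) {
    if (!nrow(doc$relations)) return(NULL)
    intra <- vapply(seq_len(nrow(doc$relations)), function(i) {
      a <- doc$entities[[doc$relations$arg1[i]]]
      b <- doc$entities[[doc$relations$arg2[i]]]
      !a$cross_sentence && !b$cross_sentence && identical(a$sentence, b$sentence)
    }, logical(1))
    data.frame(doc_id = doc$doc_id, e1 = doc$relations$arg1,
               e2 = doc$relations$arg2, rtype = doc$relations$rtype,
               intra = intra)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(doc_id = character(), e1 = character(), e2 = character(),
                      rtype = character(), intra = logical()))
  }
  do.call(rbind, rows)
}

#' Turn per-instance predicted labels into a relation set
#'
#' @param instances list of `candidate_instance`.
#' @param labels predicted category per instance (`"none"` dropped).
#' @return data.frame `doc_id`, `e1`, `e2`, `rtype`.
#' @export
predictions_to_relations <- function(instances, labels) {
  stopifnot(length(instances) == length(labels))
  keep <- labels != "none"
  data.frame(
    doc_id = vapply(instances, `[[`, character(1), "doc_id")[keep],
    e1 = vapply(instances, `[[`, character(1), "e1_id")[keep],
    e2 = vapply(instances, `[[`, character(1), "e2_id")[keep],
    rtype = labels[keep]
  )
}
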