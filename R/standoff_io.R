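# BioNLP-ST standoff corpus I/O.
#
# Offset convention throughout: 0-based, half-open [start, end), counted over
# the raw document text including newlines. R string functions are 1-based,
# so a span (start, end) corresponds to substr(text, start + 1, end).

slice <- function(text, start, end) substr(text, start + 1L, end)

#' Read a standoff-annotated document
#'
#' Parses a BioNLP-ST document from its raw text, `.a1` entity annotations
#' and (optionally) `.a2` relation annotations.
#'
#' Entity lines follow `T<id>\tab<Type> <start> <end>\tab<surface>`.
#' Discontinuous spans (`<Type> s1 e1;s2 e2`) are collapsed to their envelope
#' `[min start, max end)` with a warning. Relation lines follow
#' `R<id>\tab<Type> <Role1>:T<i> <Role2>:T<j>`; the positional dialect
#' (`Arg1:`/`Arg2:`) is accepted too. Every entity surface string is verified
#' against the text slice at its offsets.
#'
#' @param txt_content document text (single string).
#' @param a1_content contents of the `.a1` file (single string, may be empty).
#' @param a2_content contents of the `.a2` file, or `NULL` when no gold
#'   relations are available (e.g. test splits).
#' @param doc_id document identifier.
#' @return a `biorel_document`: a list with `doc_id`, `text`, `entities`
#'   (list of entity records), `relations` (data.frame with columns `id`,
#'   `rtype`, `arg1`, `arg2`) and `sentences` (empty until
#'   [attach_parses()] is called).
#' @export
read_standoff <- function(txt_content, a1_content = "", a2_content = NULL,
                          doc_id = "doc") {
  stopifnot(is.character(txt_content), length(txt_content) == 1L)
  entities <- parse_a1(a1_content, txt_content, doc_id)
  relations <- parse_a2(a2_content, names(entities), doc_id)
  structure(
    list(doc_id = doc_id, text = txt_content, entities = entities,
         relations = relations, sentences = list()),
    class = "biorel_document"
  )
}

#' @export
print.biorel_document <- function(x, ...) {
  cat(sprintf("<biorel_document '%s': %d chars, %d entities, %d relations, %d sentences>\n",
              x$doc_id, nchar(x$text), length(x$entities), nrow(x$relations),
              length(x$sentences)))
  invisible(x)
}

parse_a1 <- function(a1_content, text, doc_id) {
  lines <- split_ann_lines(a1_content)
  entities <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L || !grepl("^T[0-9]+$", parts[1]))
      stopf("%s.a1 line %d: malformed entity line: '%s'", doc_id, i, ln)
    id <- parts[1]
    head_bits <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    etype <- head_bits[1]
    span_str <- paste(head_bits[-1], collapse = " ")
    frags <- lapply(strsplit(span_str, ";", fixed = TRUE)[[1]], function(f) {
      nums <- suppressWarnings(as.integer(strsplit(trimws(f), " ")[[1]]))
      if (length(nums) != 2L || anyNA(nums))
        stopf("%s.a1 line %d: bad offsets in '%s'", doc_id, i, ln)
      nums
    })
    if (length(frags) > 1L)
      warnf("%s: discontinuous entity %s collapsed to envelope", doc_id, id)
    start <- min(vapply(frags, `[`, integer(1), 1L))
    end <- max(vapply(frags, `[`, integer(1), 2L))
    if (start >= end)
      stopf("%s.a1 line %d: empty or inverted span %d..%d", doc_id, i, start, end)
    surface <- parts[3]
    # a continuous span must match the text; an envelope need only cover it
    if (length(frags) == 1L && slice(text, start, end) != surface)
      stopf("%s.a1 line %d: surface '%s' does not match text slice '%s' at [%d,%d)",
            doc_id, i, surface, slice(text, start, end), start, end)
    if (!is.null(entities[[id]]))
      stopf("%s.a1: duplicate entity id %s", doc_id, id)
    entities[[id]] <- list(id = id, etype = etype, start = start, end = end,
                           surface = surface, sentence = NA_integer_,
                           token_span = NULL, cross_sentence = FALSE)
  }
  entities
}

parse_a2 <- function(a2_content, entity_ids, doc_id) {
  rel <- data.frame(id = character(), rtype = character(),
                    arg1 = character(), arg2 = character())
  if (is.null(a2_content)) return(rel)
  lines <- split_ann_lines(a2_content)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !grepl("^R[0-9]+$", parts[1]))
      stopf("%s.a2 line %d: malformed relation line: '%s'", doc_id, i, ln)
    bits <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    if (length(bits) != 3L || !all(grepl(":", bits[2:3], fixed = TRUE)))
      stopf("%s.a2 line %d: expected '<Type> <Role>:T<i> <Role>:T<j>': '%s'",
            doc_id, i, ln)
    args <- vapply(bits[2:3], function(b) strsplit(b, ":", fixed = TRUE)[[1]][2],
                   character(1), USE.NAMES = FALSE)
    missing <- setdiff(args, entity_ids)
    if (length(missing))
      stopf("%s.a2 line %d: argument id(s) %s not found in .a1",
            doc_id, i, paste(missing, collapse = ", "))
    rel <- rbind(rel, data.frame(id = parts[1], rtype = bits[1],
                                 arg1 = args[1], arg2 = args[2]))
  }
  rel
}

split_ann_lines <- function(content) {
  if (is.null(content) || !nzchar(trimws(content))) return(character())
  lines <- strsplit(content, "\n", fixed = TRUE)[[1]]
  lines[nzchar(trimws(lines))]
}

#' Serialize a document back to standoff format
#'
#' Inverse of [read_standoff()]: emits the `.a1` and `.a2` file contents for
#' a document. Round-trips: `read_standoff()` of the output reproduces the
#' entities and relations exactly.
#'
#' @param doc a `biorel_document`.
#' @param rules optional [task_config()]; when given, `.a2` argument roles
#'   use the task's role names, otherwise `Arg1:`/`Arg2:`.
#' @return list with elements `txt`, `a1`, `a2` (single strings).
#' @export
write_standoff <- function(doc, rules = NULL) {
  a1 <- vapply(doc$entities, function(e) {
    sprintf("%s\t%s %d %d\t%s", e$id, e$etype, e$start, e$end, e$surface)
  }, character(1), USE.NAMES = FALSE)
  a2 <- character()
  if (nrow(doc$relations)) {
    a2 <- vapply(seq_len(nrow(doc$relations)), function(i) {
      r <- doc$relations[i, ]
      format_relation_line(r$id, r$rtype, doc$entities[[r$arg1]],
                           doc$entities[[r$arg2]], rules)
    }, character(1))
  }
  list(txt = doc$text,
       a1 = paste0(a1, collapse = "\n"),
       a2 = paste0(a2, collapse = "\n"))
}

format_relation_line <- function(id, rtype, ent1, ent2, rules) {
  roles <- c("Arg1", "Arg2")
  if (!is.null(rules)) {
    cc <- NULL
    for (cand in rules$categories) if (cand$name == rtype) cc <- cand
    if (is.null(cc)) stopf("relation category '%s' not in task '%s'", rtype, rules$name)
    roles <- cc$roles
    # orient arguments so that role1's declared types come first
    for (p in cc$pairs) {
      if (match_type(p[1], ent2$etype) && match_type(p[2], ent1$etype) &&
          !(match_type(p[1], ent1$etype) && match_type(p[2], ent2$etype))) {
        tmp <- ent1; ent1 <- ent2; ent2 <- tmp
        break
      }
    }
  }
  sprintf("%s\t%s %s:%s %s:%s", id, rtype, roles[1], ent1$id, roles[2], ent2$id)
}

#' Write predicted relations as .a2 content
#'
#' @param doc a `biorel_document` whose entities the predictions refer to.
#' @param predicted data.frame with columns `rtype`, `arg1`, `arg2` (entity
#'   ids); rows with `rtype == "none"` are dropped.
#' @param rules optional [task_config()] controlling role names; predictions
#'   with a category unknown to the task raise an error.
#' @return `.a2` file content as a single string; relation ids run
#'   sequentially from `R1`.
#' @export
write_predictions <- function(doc, predicted, rules = NULL) {
  if (is.null(predicted) || nrow(predicted) == 0L) return("")
  predicted <- predicted[predicted$rtype != "none", , drop = FALSE]
  if (nrow(predicted) == 0L) return("")
  missing <- setdiff(unique(c(predicted$arg1, predicted$arg2)), names(doc$entities))
  if (length(missing))
    stopf("prediction references unknown entity id(s): %s", paste(missing, collapse = ", "))
  lines <- vapply(seq_len(nrow(predicted)), function(i) {
    r <- predicted[i, ]
    format_relation_line(sprintf("R%d", i), r$rtype,
                         doc$entities[[r$arg1]], doc$entities[[r$arg2]], rules)
  }, character(1))
  paste0(lines, collapse = "\n")
}

#' Read and write whole corpus directories
#'
#' A corpus directory holds, per document id `X`: `X.txt`, `X.a1`, optionally
#' `X.a2`, and optionally the parse sidecar `X.parse` (see [read_parses()]).
#'
#' @param dir directory path.
#' @param attach when `TRUE` (default) parse sidecars are attached via
#'   [attach_parses()].
#' @return list of `biorel_document`.
#' @export
read_corpus_dir <- function(dir, attach = TRUE) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(tf) {
    id <- sub("\\.txt$", "", basename(tf))
    base <- file.path(dir, id)
    a2 <- if (file.exists(paste0(base, ".a2"))) read_file(paste0(base, ".a2")) else NULL
    doc <- read_standoff(read_file(tf),
                         if (file.exists(paste0(base, ".a1"))) read_file(paste0(base, ".a1")) else "",
                         a2, doc_id = id)
    pf <- paste0(base, ".parse")
    if (attach && file.exists(pf)) doc <- attach_parses(doc, read_parses(read_file(pf)))
    doc
  })
}

#' @rdname read_corpus_dir
#' @param docs list of `biorel_document`.
#' @param rules optional [task_config()] for `.a2` role names.
#' @export
write_corpus_dir <- function(docs, dir, rules = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in docs) {
    out <- write_standoff(doc, rules)
    base <- file.path(dir, doc$doc_id)
    write_file(out$txt, paste0(base, ".txt"))
    write_file(out$a1, paste0(base, ".a1"))
    write_file(out$a2, paste0(base, ".a2"))
    if (length(doc$sentences))
      write_file(format_parses(doc$sentences, doc$doc_id), paste0(base, ".parse"))
  }
  invisible(dir)
}

read_file <- function(path) {
  paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
}

write_file <- function(content, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(content, con = con, sep = "\n", useBytes = TRUE)
}
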