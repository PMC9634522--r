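# Shared fixtures, all built in code.

# Compose a document text + parse sidecar + .a1 from token lists.
# sentences: list of lists with words, pos, heads, deprels.
# entities: list of lists with id, etype, sent, tokens (token index range).
make_fixture <- function(sentences, entities = list(), a2_lines = character()) {
  text <- ""
  parse <- "# doc_id = fix"
  offset <- 0L
  starts_all <- list()
  ends_all <- list()
  for (si in seq_along(sentences)) {
    s <- sentences[[si]]
    n <- length(s$words)
    pos <- s$pos %||% rep("NN", n)
    heads <- s$heads %||% c(0L, rep(1L, n - 1L))
    deprels <- s$deprels %||% c("root", rep("dep", n - 1L))
    starts <- offset + cumsum(c(0L, nchar(s$words[-n]) + 1L))
    ends <- starts + nchar(s$words)
    starts_all[[si]] <- starts; ends_all[[si]] <- ends
    text <- paste0(text, if (nzchar(text)) " " else "",
                   paste(s$words, collapse = " "))
    parse <- c(parse, sprintf("%d\t%s\t%s\t%d\t%s\t%d\t%d", seq_len(n),
                              s$words, pos, heads, deprels, starts, ends), "")
    offset <- ends[n] + 1L
  }
  a1 <- vapply(entities, function(e) {
    st <- starts_all[[e$sent]][e$tokens[1]]
    en <- ends_all[[e$sent]][e$tokens[length(e$tokens)]]
    sprintf("%s\t%s %d %d\t%s", e$id, e$etype, st, en,
            substr(text, st + 1L, en))
  }, character(1))
  list(text = text, a1 = paste(a1, collapse = "\n"),
       a2 = paste(a2_lines, collapse = "\n"),
       parse = paste(parse, collapse = "\n"))
}

read_fixture <- function(fx, doc_id = "fix") {
  doc <- read_standoff(fx$text, fx$a1, if (nzchar(fx$a2)) fx$a2 else NULL,
                       doc_id = doc_id)
  attach_parses(doc, read_parses(fx$parse))
}

# A sentence patterned after the canonical dependency-path example:
# microorganism subject, copular "cause" construction, phenotype modifier.
# Shortest path Enterococcus -> cause -> infection -> Gram-positive with
# dependency types (nsubj, prep_of, amod).
fig_path_fixture <- function() {
  make_fixture(
    sentences = list(list(
      words = c("Enterococcus", "is", "a", "cause", "of", "Gram-positive",
                "infection"),
      pos = c("NN", "VB", "DT", "NN", "IN", "JJ", "NN"),
      heads = c(4L, 4L, 4L, 0L, 4L, 7L, 4L),
      deprels = c("nsubj", "cop", "det", "root", "advmod", "amod", "prep_of"))),
    entities = list(
      list(id = "T1", etype = "Microorganism", sent = 1L, tokens = 1L),
      list(id = "T2", etype = "Phenotype", sent = 1L, tokens = 6L))
  )
}

small_dims <- function() feature_dims(word = 32L, pos = 8L, etype = 8L,
                                      dist = 8L, deptype = 16L)

small_model_config <- function(...) {
  model_config(dims = small_dims(), sent_filters = 16L, sdp_filters = 16L,
               sent_hidden = 16L, sdp_hidden = 16L, ...)
}

small_experiment_config <- function(seed = 1L, ...) {
  experiment_config(
    seed = seed,
    model = list(dims = list(word = 32L, pos = 8L, etype = 8L, dist = 8L,
                             deptype = 16L),
                 sent_filters = 16L, sdp_filters = 16L,
                 sent_hidden = 16L, sdp_hidden = 16L),
    ...)
}

# Instances + vocabulary from a small generated corpus, cached per session.
cached_instances <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      corpus <- generate_corpus(synth_config(seed = 11, n_docs = 15))
      task <- corpus$task
      inst <- unlist(lapply(corpus$documents, enumerate_candidates,
                            rules = task), recursive = FALSE)
      inst <- filter_no_path(inst, quiet = TRUE)
      vt <- build_vocabulary(inst, task$entity_types, k = 1000,
                             dims = small_dims(), seed = 2)
      cache <<- list(corpus = corpus, task = task, inst = inst,
                     vocab = vt$vocab, tables = vt$tables)
    }
    cache
  }
})

# Minimal labeled pseudo-instances for subsampling/statistics tests.
label_only_instances <- function(labels) {
  lapply(labels, function(l) structure(list(label = l),
                                       class = "candidate_instance"))
}
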