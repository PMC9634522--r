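# Seed-deterministic synthetic corpus generator.
#
# Emulates the statistical shape of the target corpora — negatives dominate,
# relations are intrasentence, shortest-dependency-path lengths concentrate
# on 2-5 — with a controllable planted signal: a legal entity pair is
# positive with a fixed probability when its dependency path is short enough
# to carry a trigger word, and positives get a trigger lemma planted on an
# interior token of their path. The mutual information between path content
# and label is therefore a generator dial, which is what makes end-to-end
# learnability testable. No linguistic realism is attempted: token surfaces
# are Zipf-distributed pseudo-words and parses are random attachment trees.

#' Synthetic corpus configuration
#'
#' @param seed RNG seed; the corpus is a pure function of the config.
#' @param n_docs number of documents.
#' @param sentences_per_doc candidate sentence counts (sampled uniformly).
#' @param sent_len token-count range per sentence.
#' @param ent_counts per-sentence entity counts, sampled with
#'   `ent_count_probs`.
#' @param ent_count_probs sampling weights for `ent_counts`.
#' @param two_token_prob probability an entity spans two tokens.
#' @param type_weights named sampling weights over entity types.
#' @param vocab_size pseudo-word lexicon size (Zipf-distributed frequencies).
#' @param ent_lexicon_size per-type entity-name lexicon size; entity surface
#'   tokens are drawn from their type's own lexicon, mirroring real corpora
#'   where surface forms are type-indicative (taxon names vs habitat nouns).
#' @param triggers trigger lemmas that carry the planted relation signal.
#' @param p_pos probability that an eligible legal pair is made positive.
#' @param eligible_m dependency-path length (token count) range within which
#'   a pair may be positive.
#' @param noise_rate probability a positive is planted without its trigger
#'   (label noise for the path signal).
#' @param distractor_rate probability a sentence gets a trigger word on a
#'   random non-entity, non-path token (off-path false signal).
#' @param forest_prob probability a sentence's parse is broken into two
#'   components (exercises the no-path filter; 0 by default so parses are
#'   connected trees).
#' @param intersentence_rate probability a two-sentence document gets one
#'   additional cross-sentence gold relation (excluded from candidates
#'   downstream, matching the intrasentence-only design).
#' @param task a [task_config()]; defaults to the Bacteria-Biotope rules.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_docs = 200L,
                         sentences_per_doc = 3:5,
                         sent_len = c(8L, 30L),
                         ent_counts = c(2L, 3L),
                         ent_count_probs = c(0.6, 0.4),
                         two_token_prob = 0.15,
                         type_weights = c(Microorganism = 0.45, Habitat = 0.20,
                                          Geographical = 0.08, Phenotype = 0.27),
                         vocab_size = 300L,
                         ent_lexicon_size = 40L,
                         triggers = c("trigax", "trigbex", "trigcun"),
                         p_pos = 0.6,
                         eligible_m = c(3L, 5L),
                         noise_rate = 0.05,
                         distractor_rate = 0.2,
                         forest_prob = 0,
                         intersentence_rate = 0.05,
                         task = NULL) {
  stopifnot(p_pos >= 0, p_pos <= 1, noise_rate >= 0, noise_rate <= 1,
            vocab_size > 10L, n_docs >= 0L)
  if (!length(type_weights)) stopf("entity-type inventory must not be empty")
  structure(
    list(seed = seed, n_docs = n_docs, sentences_per_doc = sentences_per_doc,
         sent_len = sent_len, ent_counts = ent_counts,
         ent_count_probs = ent_count_probs, two_token_prob = two_token_prob,
         type_weights = type_weights, vocab_size = vocab_size,
         ent_lexicon_size = ent_lexicon_size, triggers = triggers, p_pos = p_pos, eligible_m = eligible_m,
         noise_rate = noise_rate, distractor_rate = distractor_rate,
         forest_prob = forest_prob, intersentence_rate = intersentence_rate,
         task = task),
    class = "synth_config"
  )
}

SYNTH_DEPRELS <- c("nsubj", "dobj", "amod", "det", "prep_of", "advmod",
                   "cop", "conj", "nmod")
SYNTH_POS <- c("NN", "VB", "JJ", "DT", "IN", "RB")

#' Generate a synthetic standoff corpus
#'
#' Produces complete documents (text, entities, gold relations, attached
#' dependency parses) plus a manifest of the planting ground truth. The
#' documents are built by serializing to standoff + parse-sidecar text and
#' re-reading them through [read_standoff()] and [attach_parses()], so the
#' generated corpus is consistent with the package's own I/O by
#' construction.
#'
#' @param config a [synth_config()].
#' @return list with `documents` (list of `biorel_document`), `task` (the
#'   [task_config()] used) and `manifest` (planted positive/negative/
#'   eligible pair counts, SDP-length histogram, intersentence relation
#'   count, seed).
#' @export
generate_corpus <- function(config = synth_config()) {
  task <- config$task %||% bbrel_task()
  withr::with_seed(config$seed, {
    lexicon <- sprintf("w%04d", seq_len(config$vocab_size))
    zipf <- 1 / seq_len(config$vocab_size)^1.1
    ent_lex <- lapply(stats::setNames(nm = names(config$type_weights)), function(ty)
      sprintf("%s%03d", tolower(substr(ty, 1, 3)), seq_len(config$ent_lexicon_size)))
    docs <- list()
    man <- list(n_pos = 0L, n_neg = 0L, n_eligible = 0L, n_pairs = 0L,
                sdp_hist = integer(), n_intersentence = 0L, n_sentences = 0L)
    for (d in seq_len(config$n_docs)) {
      doc_id <- sprintf("d%04d", d)
      n_sent <- sample_one(config$sentences_per_doc)
      sents <- lapply(seq_len(n_sent), function(i)
        gen_sentence(config, task, lexicon, zipf, ent_lex))
      man$n_sentences <- man$n_sentences + n_sent
      for (s in sents) {
        man$n_pos <- man$n_pos + s$n_pos
        man$n_neg <- man$n_neg + s$n_neg
        man$n_eligible <- man$n_eligible + s$n_eligible
        man$n_pairs <- man$n_pairs + s$n_pos + s$n_neg
        for (m in s$sdp_m) {
          key <- as.character(m)
          prev <- man$sdp_hist[key]
          man$sdp_hist[key] <- (if (is.na(prev)) 0L else prev) + 1L
        }
      }
      doc <- assemble_doc(doc_id, sents, config)
      man$n_intersentence <- man$n_intersentence + attr(doc, "n_intersentence")
      docs[[doc_id]] <- doc
    }
    man$seed <- config$seed
    man$n_docs <- config$n_docs
    list(documents = docs, task = task, manifest = man)
  })
}

sample_one <- function(x, prob = NULL) {
  if (length(x) == 1L) return(x)
  sample(x, 1L, prob = prob)
}

gen_sentence <- function(cfg, task, lexicon, zipf, ent_lex) {
  n <- sample_one(seq(cfg$sent_len[1], cfg$sent_len[2]))
  words <- sample(lexicon, n, replace = TRUE, prob = zipf)
  pos <- sample(SYNTH_POS, n, replace = TRUE)
  heads <- c(0L, vapply(2:n, function(i) sample_one(seq_len(i - 1L)), integer(1)))
  deprels <- sample(SYNTH_DEPRELS, n, replace = TRUE)
  deprels[1] <- "root"
  if (stats::runif(1) < cfg$forest_prob && n > 3L) {
    cut <- sample_one(2:n)
    heads[cut] <- 0L       # second root: the parse becomes a two-tree forest
    deprels[cut] <- "root"
  }
  # place entities on non-adjacent free tokens
  k <- sample_one(cfg$ent_counts, prob = cfg$ent_count_probs)
  taken <- logical(n)
  spans <- list()
  for (i in seq_len(k)) {
    free <- which(!taken)
    if (!length(free)) break
    t0 <- sample_one(free)
    span <- c(t0, t0)
    if (stats::runif(1) < cfg$two_token_prob && t0 < n && !taken[t0 + 1L])
      span[2] <- t0 + 1L
    taken[span[1]:span[2]] <- TRUE
    spans[[length(spans) + 1L]] <- span
  }
  spans <- spans[order(vapply(spans, `[`, integer(1), 1L))]
  types <- sample(names(cfg$type_weights), length(spans), replace = TRUE,
                  prob = cfg$type_weights)
  for (e in seq_along(spans)) {
    sp <- spans[[e]]
    lex <- ent_lex[[types[e]]]
    words[sp[1]:sp[2]] <- sample(lex, sp[2] - sp[1] + 1L,
                                 prob = 1 / seq_along(lex))
  }
  pos[unlist(lapply(spans, function(s) s[1]:s[2]))] <- "NN"

  edges <- data.frame(head = heads[heads != 0L],
                      dep = which(heads != 0L),
                      deprel = deprels[heads != 0L])
  graph <- build_undirected_graph(sentence_graph(
    data.frame(form = words, pos = pos,
               start = cumsum(c(0L, nchar(words[-n]) + 1L)),
               end = cumsum(nchar(words) + seq_len(n) - seq_len(n)) +
                     cumsum(c(0L, rep(1L, n - 1L)))),
    edges))

  ent_tokens <- unlist(lapply(spans, function(s) s[1]:s[2]))
  relations <- list()
  n_pos <- 0L; n_neg <- 0L; n_eligible <- 0L
  sdp_m <- integer()
  # paths of every legal candidate pair, computed up front so that trigger
  # and distractor placement can keep the planted rule clean: a trigger lies
  # on a pair's path iff that pair is positive (up to the noise rate)
  pairs <- list()
  if (length(spans) >= 2L) {
    for (i in seq_len(length(spans) - 1L)) {
      for (j in seq((i + 1L), length(spans))) {
        cats <- legal_categories(task, types[i], types[j])
        if (!length(cats)) next
        p <- shortest_dependency_path(graph, spans[[i]][2], spans[[j]][2])
        pairs[[length(pairs) + 1L]] <- list(i = i, j = j, cat = cats[1], path = p)
        if (!is.null(p)) sdp_m <- c(sdp_m, p$m)
      }
    }
  }
  all_path_tokens <- unique(unlist(lapply(pairs, function(pp) pp$path$token_idx)))
  # a pair is eligible to be positive when its path is short enough AND has
  # an interior token private to it (on no other candidate's path), so a
  # planted trigger marks exactly one pair's path and the generating rule
  # "related iff a trigger lies on the pair's dependency path" holds exactly,
  # up to the configured noise rate
  positive <- logical(length(pairs))
  private <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    pp <- pairs[[k]]
    if (is.null(pp$path)) next
    other <- unique(unlist(lapply(pairs[-k], function(q) q$path$token_idx)))
    private[[k]] <- setdiff(setdiff(pp$path$token_idx, ent_tokens), other)
    eligible <- pp$path$m >= cfg$eligible_m[1] && pp$path$m <= cfg$eligible_m[2] &&
      length(private[[k]]) > 0L
    if (eligible) n_eligible <- n_eligible + 1L
    positive[k] <- eligible && stats::runif(1) < cfg$p_pos
  }
  n_pos <- sum(positive)
  n_neg <- length(pairs) - n_pos
  for (k in which(positive)) {
    pp <- pairs[[k]]
    relations[[length(relations) + 1L]] <- list(i = pp$i, j = pp$j, cat = pp$cat)
    if (stats::runif(1) >= cfg$noise_rate) {
      tt <- sample_one(private[[k]])
      words[tt] <- sample_one(cfg$triggers)
      pos[tt] <- "VB"
    }
  }
  if (stats::runif(1) < cfg$distractor_rate) {
    cand <- setdiff(seq_len(n), union(ent_tokens, all_path_tokens))
    if (length(cand)) words[sample_one(cand)] <- sample_one(cfg$triggers)
  }
  list(words = words, pos = pos, heads = heads, deprels = deprels,
       spans = spans, types = types, relations = relations,
       n_pos = n_pos, n_neg = n_neg, n_eligible = n_eligible, sdp_m = sdp_m)
}

# Serialize generated sentences to standoff + sidecar text and re-read them,
# so every generated document passes the package's own integrity checks.
assemble_doc <- function(doc_id, sents, cfg) {
  text <- ""
  a1 <- character(); a2 <- character()
  parse_lines <- c(sprintf("# doc_id = %s", doc_id))
  te <- 0L  # entity counter
  tr <- 0L  # relation counter
  ent_ids <- list()  # per sentence: entity ids
  offset <- 0L
  for (si in seq_along(sents)) {
    s <- sents[[si]]
    n <- length(s$words)
    starts <- offset + cumsum(c(0L, nchar(s$words[-n]) + 1L))
    ends <- starts + nchar(s$words)
    text <- paste0(text, if (nzchar(text)) " " else "", paste(s$words, collapse = " "))
    parse_lines <- c(parse_lines,
                     sprintf("%d\t%s\t%s\t%d\t%s\t%d\t%d", seq_len(n), s$words,
                             s$pos, s$heads, s$deprels, starts, ends),
                     "")
    ids <- character(length(s$spans))
    for (e in seq_along(s$spans)) {
      sp <- s$spans[[e]]
      te <- te + 1L
      ids[e] <- sprintf("T%d", te)
      surface <- paste(s$words[sp[1]:sp[2]], collapse = " ")
      a1 <- c(a1, sprintf("%s\t%s %d %d\t%s", ids[e], s$types[e],
                          starts[sp[1]], ends[sp[2]], surface))
    }
    ent_ids[[si]] <- ids
    for (r in s$relations) {
      tr <- tr + 1L
      a2 <- c(a2, sprintf("R%d\t%s Arg1:%s Arg2:%s", tr, r$cat,
                          ids[r$i], ids[r$j]))
    }
    offset <- ends[n] + 1L
  }
  n_inter <- 0L
  if (length(sents) >= 2L && stats::runif(1) < cfg$intersentence_rate &&
      length(ent_ids[[1]]) && length(ent_ids[[2]])) {
    # one cross-sentence gold relation; never yields a candidate instance
    i1 <- sample_one(seq_along(ent_ids[[1]]))
    i2 <- sample_one(seq_along(ent_ids[[2]]))
    cats <- legal_categories(cfg$task %||% bbrel_task(),
                             sents[[1]]$types[i1], sents[[2]]$types[i2])
    if (length(cats)) {
      tr <- tr + 1L
      a2 <- c(a2, sprintf("R%d\t%s Arg1:%s Arg2:%s", tr, cats[1],
                          ent_ids[[1]][i1], ent_ids[[2]][i2]))
      n_inter <- 1L
    }
  }
  doc <- read_standoff(text, paste(a1, collapse = "\n"),
                       paste(a2, collapse = "\n"), doc_id = doc_id)
  doc <- attach_parses(doc, read_parses(paste(parse_lines, collapse = "\n")))
  attr(doc, "n_intersentence") <- n_inter
  doc
}

#' Generate a random word2vec-format embedding table
#'
#' Unit-norm random vectors, deterministic per seed; a stand-in (synthetic)
#' for pretrained embeddings in tests and pipelines.
#'
#' @param words character vector of words, or an integer count (words are
#'   then `w0001`, `w0002`, ...).
#' @param d embedding dimension.
#' @param seed RNG seed.
#' @return numeric matrix with `words` as rownames (write with
#'   [write_word2vec()]).
#' @export
generate_embeddings <- function(words, d, seed = 1L) {
  stopifnot(d > 0)
  if (is.numeric(words)) words <- sprintf("w%04d", seq_len(words))
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(length(words) * d), length(words), d)
    m <- m / sqrt(rowSums(m^2))
    rownames(m) <- words
    m
  })
}
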