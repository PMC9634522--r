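bb <- bbrel_task()

two_entity_fixture <- function(t1, t2, a2_lines = character()) {
  fx <- make_fixture(
    sentences = list(list(words = c("mica01", "lives", "in", "haba01"),
                          heads = c(2L, 0L, 2L, 2L),
                          deprels = c("nsubj", "root", "advmod", "dobj"))),
    entities = list(list(id = "T1", etype = t1, sent = 1L, tokens = 1L),
                    list(id = "T2", etype = t2, sent = 1L, tokens = 4L)),
    a2_lines = a2_lines)
  read_fixture(fx)
}

test_that("an unannotated legal pair yields one nonrelation instance", {
  inst <- enumerate_candidates(two_entity_fixture("Microorganism", "Habitat"), bb)
  expect_length(inst, 1)
  expect_equal(inst[[1]]$label, "none")
  expect_equal(inst[[1]]$e1_id, "T1")
})

test_that("type-constraint-violating pairs yield no instance", {
  inst <- enumerate_candidates(two_entity_fixture("Geographical", "Phenotype"), bb)
  expect_length(inst, 0)
})

test_that("gold-annotated pairs carry their category", {
  doc <- two_entity_fixture("Microorganism", "Habitat",
                            "R1\tLives_In Microorganism:T1 Location:T2")
  inst <- enumerate_candidates(doc, bb)
  expect_length(inst, 1)
  expect_equal(inst[[1]]$label, "Lives_In")
})

test_that("an illegal gold label is kept with a warning (corpus over rules)", {
  doc <- two_entity_fixture("Microorganism", "Habitat",
                            "R1\tExhibits Arg1:T1 Arg2:T2")
  expect_warning(inst <- enumerate_candidates(doc, bb), "do not license")
  expect_equal(inst[[1]]$label, "Exhibits")
})

test_that("intersentence gold relations produce no instance", {
  fx <- make_fixture(
    sentences = list(list(words = c("mica01", "x")),
                     list(words = c("haba01", "y"))),
    entities = list(list(id = "T1", etype = "Microorganism", sent = 1L, tokens = 1L),
                    list(id = "T2", etype = "Habitat", sent = 2L, tokens = 1L)),
    a2_lines = "R1\tLives_In Arg1:T1 Arg2:T2")
  inst <- enumerate_candidates(read_fixture(fx), bb)
  expect_length(inst, 0)
})

test_that("pair enumeration equals brute-force type-legality counting", {
  corpus <- generate_corpus(synth_config(seed = 23, n_docs = 12,
                                         ent_counts = 2:6,
                                         ent_count_probs = rep(0.25, 5)))
  for (doc in corpus$documents) {
    inst <- suppressWarnings(enumerate_candidates(doc, corpus$task))
    # brute force: count legal unordered same-sentence pairs
    expected <- 0L
    for (si in seq_along(doc$sentences)) {
      ents <- Filter(function(e) identical(e$sentence, si), doc$entities)
      if (length(ents) < 2L) next
      for (i in seq_len(length(ents) - 1L)) {
        for (j in seq((i + 1L), length(ents))) {
          if (length(legal_categories(corpus$task, ents[[i]]$etype,
                                      ents[[j]]$etype)) > 0L)
            expected <- expected + 1L
        }
      }
    }
    expect_equal(length(inst), expected)
  }
})

test_that("all-compatible sentences yield k*(k-1)/2 instances", {
  for (k in 2:5) {
    types <- rep(c("Microorganism", "Habitat"), length.out = k)
    # alternate types so every adjacent-type pair is legal only when mixed;
    # use a wildcard task so every pair is legal
    wild <- task_config("wild", unique(types),
                        list(list(name = "Rel", roles = c("A", "B"),
                                  pairs = list(c("*", "*")))))
    words <- sprintf("w%02d", seq_len(k + 2))
    fx <- make_fixture(
      sentences = list(list(words = words)),
      entities = lapply(seq_len(k), function(i)
        list(id = sprintf("T%d", i), etype = types[i], sent = 1L, tokens = i)))
    inst <- enumerate_candidates(read_fixture(fx), wild)
    expect_length(inst, k * (k - 1) / 2)
  }
})

test_that("no instance pairs entities from different sentences", {
  cc <- cached_instances()
  for (x in cc$inst) {
    doc <- cc$corpus$documents[[x$doc_id]]
    expect_equal(doc$entities[[x$e1_id]]$sentence,
                 doc$entities[[x$e2_id]]$sentence)
  }
})

test_that("filter_no_path removes exactly the disconnected pairs", {
  # connected trees: nothing removed
  cc <- cached_instances()
  expect_length(filter_no_path(cc$inst, quiet = TRUE), length(cc$inst))

  # forest corpus: removals match an independent igraph connectivity oracle
  skip_if_not_installed("igraph")
  corpus <- generate_corpus(synth_config(seed = 9, n_docs = 30, forest_prob = 1))
  inst <- unlist(lapply(corpus$documents, enumerate_candidates,
                        rules = corpus$task), recursive = FALSE)
  kept <- filter_no_path(inst, quiet = TRUE)
  expect_lt(length(kept), length(inst))
  oracle_connected <- vapply(inst, function(x) {
    doc <- corpus$documents[[x$doc_id]]
    sent <- doc$sentences[[x$sentence]]
    g <- igraph::graph_from_edgelist(
      as.matrix(sent$edges[, c("head", "dep")]), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nrow(sent$tokens) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    h1 <- doc$entities[[x$e1_id]]$token_span[2]
    h2 <- doc$entities[[x$e2_id]]$token_span[2]
    comp[h1] == comp[h2]
  }, logical(1))
  expect_equal(length(kept), sum(oracle_connected))
})

test_that("negative subsampling follows the floor rule and keeps positives", {
  insts <- label_only_instances(c(rep("Lives_In", 1508),
                                  rep("none", 17489)))
  out <- subsample_negatives(insts, keep_fraction = 0.10, seed = 3)
  st <- corpus_statistics(out)
  expect_equal(st$positives, 1508)            # positives invariant
  expect_equal(17489 - st$negatives, 15740)   # floor((1-0.1) * 17489)
  expect_equal(st$negatives, 1749)

  # keep_fraction 1 is the identity
  expect_identical(subsample_negatives(insts, 1.0, seed = 1), insts)
  expect_error(subsample_negatives(insts, -0.1, seed = 1), "keep_fraction")
})

test_that("subsampling is seed-deterministic and seed-sensitive", {
  insts <- lapply(seq_len(230), function(i) {
    structure(list(label = if (i <= 30) "Exhibits" else "none", uid = i),
              class = "candidate_instance")
  })
  uid <- function(x) vapply(x, `[[`, numeric(1), "uid")
  a <- subsample_negatives(insts, 0.25, seed = 7)
  b <- subsample_negatives(insts, 0.25, seed = 7)
  c <- subsample_negatives(insts, 0.25, seed = 8)
  expect_identical(uid(a), uid(b))
  expect_equal(length(c), length(a))
  expect_false(identical(uid(a), uid(c)))
})

test_that("corpus statistics reproduce split totals", {
  expect_equal(corpus_statistics(list())$total, 0)
  bb_train <- label_only_instances(c(rep("Lives_In", 659), rep("Exhibits", 284),
                                     rep("none", 1053)))
  st <- corpus_statistics(bb_train)
  expect_equal(st$positives, 943)
  expect_equal(st$total, 1996)
  sd_train <- label_only_instances(c(rep("Regulates_Process", 1508),
                                     rep("none", 17489)))
  expect_equal(corpus_statistics(sd_train)$total, 18997)
  expect_equal(st$total, sum(st$counts))
})

test_that("instances survive a JSON-lines round trip", {
  cc <- cached_instances()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_instances_jsonl(cc$inst[1:5], path)
  back <- read_instances_jsonl(path)
  for (i in 1:5) {
    expect_equal(back[[i]]$label, cc$inst[[i]]$label)
    expect_equal(back[[i]]$tokens, cc$inst[[i]]$tokens)
    expect_equal(back[[i]]$sdp$words, cc$inst[[i]]$sdp$words)
    expect_equal(back[[i]]$dist1_seq, cc$inst[[i]]$dist1_seq)
  }
})
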