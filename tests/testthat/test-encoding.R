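test_that("relative distance is signed, scaled and monotone", {
  expect_equal(relative_distance(0, 10), 0)
  expect_equal(relative_distance(10, 10), 1)
  expect_equal(relative_distance(-10, 10), -1)
  expect_error(relative_distance(1, 0), "positive")
  expect_error(relative_distance(11, 10), "exceeds")
  for (s in c(3, 17, 50)) {
    vals <- relative_distance(seq(-s, s), s)
    expect_true(all(diff(vals) > 0))
    expect_true(all(vals >= -1 & vals <= 1))
  }
})

test_that("positional encoding matches its closed form", {
  d <- 16L
  pe <- positional_encoding(5L, d)
  # position 0: sin columns 0, cos columns 1
  expect_equal(pe[1, seq(1, d, 2)], rep(0, d / 2))
  expect_equal(pe[1, seq(2, d, 2)], rep(1, d / 2))
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)
  expect_true(all(pe >= -1 & pe <= 1))
  # independent double-loop evaluation
  ref <- matrix(0, 5, d)
  for (posn in 0:4) {
    for (i in 0:(d / 2 - 1)) {
      ref[posn + 1, 2 * i + 1] <- sin(posn / 10000^(2 * i / d))
      ref[posn + 1, 2 * i + 2] <- cos(posn / 10000^(2 * i / d))
    }
  }
  expect_equal(pe, ref, tolerance = 1e-6)
  expect_error(positional_encoding(3L, 15L), "even")
})

test_that("vocabulary construction caps size and adds placeholders", {
  cc <- cached_instances()
  toks <- unique(unlist(lapply(cc$inst, `[[`, "tokens")))
  vt <- build_vocabulary(cc$inst, cc$task$entity_types, k = 100000,
                         dims = small_dims(), seed = 1)
  # <pad> + <unk> + 4 placeholders + distinct corpus tokens
  expect_length(vt$vocab$words, length(toks) + 6L)
  expect_true(all(cc$task$entity_types %in% vt$vocab$words))
  vt5 <- build_vocabulary(cc$inst, cc$task$entity_types, k = 5,
                          dims = small_dims(), seed = 1)
  expect_length(vt5$vocab$words, 5L + 6L)
})

test_that("out-of-dictionary entity words fall back to their type placeholder", {
  cc <- cached_instances()
  vt <- build_vocabulary(cc$inst, cc$task$entity_types, k = 1000,
                         dims = small_dims(), seed = 1)
  inst <- cc$inst[[1]]
  i_ent <- which(!is.na(inst$entity_type_seq))[1]
  inst$tokens[i_ent] <- "neverseenbefore"
  i_oth <- which(is.na(inst$entity_type_seq))[1]
  inst$tokens[i_oth] <- "alsoneverseen"
  enc <- encode_instance(inst, vt$vocab, cc$task$category_names)
  etype <- inst$entity_type_seq[i_ent]
  expect_equal(enc$word_idx[i_ent], unname(vt$vocab$placeholder[[etype]]))
  expect_equal(enc$word_idx[i_oth], 2L)  # <unk>
})

test_that("random initialization is seed-deterministic", {
  cc <- cached_instances()
  a <- build_vocabulary(cc$inst, cc$task$entity_types, dims = small_dims(),
                        seed = 5)
  b <- build_vocabulary(cc$inst, cc$task$entity_types, dims = small_dims(),
                        seed = 5)
  expect_identical(a$tables, b$tables)
  d <- build_vocabulary(cc$inst, cc$task$entity_types, dims = small_dims(),
                        seed = 6)
  expect_false(identical(a$tables$word, d$tables$word))
})

test_that("pretrained embeddings fill matching rows and the rest is random", {
  cc <- cached_instances()
  words <- unique(unlist(lapply(cc$inst, `[[`, "tokens")))[1:10]
  emb <- generate_embeddings(words, d = 32L, seed = 3)
  vt <- build_vocabulary(cc$inst, cc$task$entity_types, k = 1000,
                         embeddings = emb, dims = small_dims(), seed = 1)
  for (w in words) {
    expect_equal(vt$tables$word[vt$vocab$word_index[[w]], ], unname(emb[w, ]),
                 tolerance = 1e-12)
  }
  expect_error(build_vocabulary(cc$inst, cc$task$entity_types,
                                embeddings = emb[, 1:8],
                                dims = small_dims(), seed = 1),
               "dimension")
})

test_that("default dimensions give 800 per sentence token and 400 per path token", {
  cc <- cached_instances()
  dims <- feature_dims()  # 200/200/200/100/200
  vt <- build_vocabulary(cc$inst[1:5], cc$task$entity_types, k = 200,
                         dims = dims, seed = 1)
  enc <- encode_instance(cc$inst[[1]], vt$vocab, cc$task$category_names)
  f <- instance_features(enc, vt$tables, pad_to = 4L)
  expect_equal(ncol(f$X), 800L)
  expect_equal(nrow(f$X), enc$n)
  expect_equal(ncol(f$P), 400L)
  expect_equal(nrow(f$P), max(enc$m, 4L))
})

test_that("the canonical path instance encodes a (4, d_sdp) channel with PAD-filled types", {
  doc <- read_fixture(fig_path_fixture())
  inst <- enumerate_candidates(doc, bbrel_task())[[1]]
  vt <- build_vocabulary(list(inst), bbrel_task()$entity_types,
                         dims = small_dims(), seed = 1)
  enc <- encode_instance(inst, vt$vocab, bbrel_task()$category_names)
  expect_equal(enc$m, 4L)
  expect_equal(vt$vocab$deptype[enc$sdp_dep_idx],
               c("nsubj", "prep_of", "amod", "<pad>"))
  f <- instance_features(enc, vt$tables, pad_to = 4L)
  expect_equal(dim(f$P), c(4L, small_dims()$d_sdp))
  # the padded dependency-type row contributes zeros
  expect_equal(unname(f$P[4, 32 + 1:16] - vt$tables$deptype[1, ]), rep(0, 16))
})

test_that("encoding is a pure, invertible map of token/POS/type sequences", {
  cc <- cached_instances()
  vt <- build_vocabulary(cc$inst, cc$task$entity_types, dims = small_dims(),
                         seed = 1)
  for (inst in cc$inst[1:20]) {
    enc1 <- encode_instance(inst, vt$vocab, cc$task$category_names)
    enc2 <- encode_instance(inst, vt$vocab, cc$task$category_names)
    expect_identical(enc1, enc2)
    expect_equal(vt$vocab$words[enc1$word_idx], inst$tokens)
    expect_equal(vt$vocab$pos[enc1$pos_idx], inst$pos)
    decoded_types <- vt$vocab$etype[enc1$etype_idx]
    expect_equal(decoded_types == "<none>", is.na(inst$entity_type_seq))
    expect_equal(decoded_types[decoded_types != "<none>"],
                 inst$entity_type_seq[!is.na(inst$entity_type_seq)])
    expect_true(all(abs(enc1$rel1) <= 1 & abs(enc1$rel2) <= 1))
    # scaled distances preserve the sign pattern of the raw token offsets
    expect_equal(sign(enc1$rel1), sign(inst$dist1_seq))
    expect_equal(sign(enc1$rel2), sign(inst$dist2_seq))
  }
})

test_that("word2vec text files round-trip", {
  emb <- generate_embeddings(50, d = 24L, seed = 8)
  path <- withr::local_tempfile(fileext = ".txt")
  write_word2vec(emb, path)
  lines <- readLines(path)
  expect_equal(lines[1], "50 24")
  expect_length(lines, 51L)
  back <- read_word2vec(path)
  expect_equal(back, emb, tolerance = 1e-5)
  writeLines(c("3 4", "a 1 2 3 4", "b 1 2"), path)
  expect_error(read_word2vec(path), "declares")
})
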