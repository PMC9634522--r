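tiny_setup <- function() {
  corpus <- generate_corpus(synth_config(seed = 3, n_docs = 6,
                                         sent_len = c(5L, 9L)))
  task <- corpus$task
  inst <- filter_no_path(unlist(lapply(corpus$documents, enumerate_candidates,
                                       rules = task), recursive = FALSE),
                         quiet = TRUE)
  dims <- feature_dims(8L, 4L, 4L, 4L, 4L)
  vt <- build_vocabulary(inst, task$entity_types, k = 500, dims = dims,
                         seed = 2)
  list(task = task, inst = inst, dims = dims, vocab = vt$vocab,
       tables = vt$tables)
}

test_that("analytic gradients match finite differences for every encoder variant", {
  ts <- tiny_setup()
  enc <- encode_instance(ts$inst[[2]], ts$vocab, ts$task$category_names)
  loss_of <- function(model) {
    -log(forward(model, enc)$probs[enc$label_idx])
  }
  variants <- list(c("mha", "cnn"), c("bilstm_attention", "lstm"),
                   c("cnn_attention", "none"))
  for (v in variants) {
    mcfg <- model_config(dims = ts$dims, encoder = v[1], heads = 4L,
                         sent_filters = 3L, sent_windows = c(2L, 3L),
                         sent_hidden = 4L, sdp_encoder = v[2],
                         sdp_filters = 3L, sdp_windows = c(2L, 3L),
                         sdp_hidden = 3L, dropout = 0)
    model <- model_init(ts$vocab, ts$tables, ts$task$category_names, mcfg,
                        seed = 5)
    fwd <- forward(model, enc)
    g <- biorel:::backward(model, fwd$cache, enc$label_idx)
    withr::with_seed(1, {
      for (key in names(g)) {
        p <- model$params[[key]]
        for (ii in sample(length(p), min(3L, length(p)))) {
          eps <- 1e-5
          m2 <- model
          m2$params[[key]][ii] <- p[ii] + eps
          lp <- loss_of(m2)
          m2$params[[key]][ii] <- p[ii] - eps
          lm <- loss_of(m2)
          num <- (lp - lm) / (2 * eps)
          expect_equal(g[[key]][ii], num, tolerance = 1e-4,
                       label = sprintf("d/d%s[%d] (%s+%s)", key, ii, v[1], v[2]))
        }
      }
    })
  }
})

test_that("forward produces probability rows and is deterministic in eval mode", {
  ts <- tiny_setup()
  mcfg <- model_config(dims = ts$dims, heads = 4L, sent_filters = 4L,
                       sdp_filters = 4L, sdp_windows = c(2L, 3L))
  model <- model_init(ts$vocab, ts$tables, ts$task$category_names, mcfg,
                      seed = 1)
  encs <- lapply(ts$inst[1:6], encode_instance, vocab = ts$vocab,
                 categories = ts$task$category_names)
  for (enc in encs) {
    p1 <- forward(model, enc)$probs
    p2 <- forward(model, enc)$probs
    expect_equal(sum(p1), 1, tolerance = 1e-6)
    expect_true(all(p1 >= 0))
    expect_identical(p1, p2)  # dropout is inert outside training
  }
  probs <- predict(model, encs)
  expect_equal(dim(probs), c(6L, 3L))
  expect_equal(colnames(probs), ts$task$category_names)
})

test_that("softmax rows match an exp/normalize loop on random logits", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      x <- rnorm(sample(2:6, 1), sd = 3)
      ref <- exp(x) / sum(exp(x))
      expect_equal(biorel:::softmax_vec(x), ref, tolerance = 1e-12)
    }
  })
})

test_that("initial loss on balanced classes is close to ln(C)", {
  ts <- tiny_setup()
  mcfg <- model_config(dims = ts$dims, heads = 4L, sent_filters = 4L,
                       sdp_filters = 4L, sdp_windows = c(2L, 3L))
  model <- model_init(ts$vocab, ts$tables, ts$task$category_names, mcfg,
                      seed = 9)
  encs <- lapply(ts$inst, encode_instance, vocab = ts$vocab,
                 categories = ts$task$category_names)
  # balanced by construction: cycle the gold label over the C categories
  losses <- vapply(seq_along(encs), function(i) {
    -log(forward(model, encs[[i]])$probs[(i %% 3L) + 1L])
  }, numeric(1))
  expect_equal(mean(losses), log(3), tolerance = 0.25)
})

test_that("training is seed-deterministic end to end", {
  ts <- tiny_setup()
  encs <- lapply(ts$inst, encode_instance, vocab = ts$vocab,
                 categories = ts$task$category_names)
  split <- seq_along(encs) %% 3L == 0L
  mcfg <- model_config(dims = ts$dims, heads = 4L, sent_filters = 4L,
                       sdp_filters = 4L, sdp_windows = c(2L, 3L))
  tcfg <- train_config(max_epochs = 2L, seeds = 1L)
  m1 <- train_one(encs[!split], encs[split], ts$vocab, ts$tables,
                  ts$task$category_names, mcfg, tcfg, seed = 4L)
  m2 <- train_one(encs[!split], encs[split], ts$vocab, ts$tables,
                  ts$task$category_names, mcfg, tcfg, seed = 4L)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  m3 <- train_one(encs[!split], encs[split], ts$vocab, ts$tables,
                  ts$task$category_names, mcfg, tcfg, seed = 5L)
  expect_false(identical(m3$history, m1$history))
})

test_that("early stopping restores the best validation epoch", {
  ts <- tiny_setup()
  encs <- lapply(ts$inst, encode_instance, vocab = ts$vocab,
                 categories = ts$task$category_names)
  split <- seq_along(encs) %% 3L == 0L
  mcfg <- model_config(dims = ts$dims, heads = 4L, sent_filters = 4L,
                       sdp_filters = 4L, sdp_windows = c(2L, 3L))
  m <- train_one(encs[!split], encs[split], ts$vocab, ts$tables,
                 ts$task$category_names, mcfg,
                 train_config(max_epochs = 6L, patience = 2L, seeds = 1L),
                 seed = 2L)
  expect_true(nrow(m$history) >= 1L)
  expect_equal(m$val_f1, max(m$history$val_f1))
  expect_equal(m$selected_epoch, which.max(m$history$val_f1))
  expect_error(
    train_one(encs[!split], encs[split][rep(which(
      vapply(encs[split], function(e) e$label_idx == 3L, logical(1)))[1], 2)],
      ts$vocab, ts$tables, ts$task$category_names, mcfg,
      train_config(seeds = 1L), seed = 1L),
    "no positive")
})

test_that("multi-seed selection returns the argmax with correct statistics", {
  ts <- tiny_setup()
  encs <- lapply(ts$inst, encode_instance, vocab = ts$vocab,
                 categories = ts$task$category_names)
  split <- seq_along(encs) %% 3L == 0L
  mcfg <- model_config(dims = ts$dims, heads = 4L, sent_filters = 4L,
                       sdp_filters = 4L, sdp_windows = c(2L, 3L))
  tcfg <- train_config(max_epochs = 2L, seeds = c(1L, 2L, 3L))
  best <- multi_seed_select(encs[!split], encs[split], ts$vocab, ts$tables,
                            ts$task$category_names, mcfg, tcfg)
  ss <- best$seed_summary
  expect_length(ss$f1_by_seed, 3L)
  expect_equal(best$val_f1, max(ss$f1_by_seed))
  expect_equal(ss$mean, mean(ss$f1_by_seed))
  expect_equal(ss$sd, sqrt(sum((ss$f1_by_seed - mean(ss$f1_by_seed))^2) / 2))

  # one seed degenerates to train_one
  one <- multi_seed_select(encs[!split], encs[split], ts$vocab, ts$tables,
                           ts$task$category_names, mcfg,
                           train_config(max_epochs = 2L, seeds = 2L))
  ref <- train_one(encs[!split], encs[split], ts$vocab, ts$tables,
                   ts$task$category_names, mcfg,
                   train_config(max_epochs = 2L, seeds = 2L), seed = 2L)
  expect_identical(one$params, ref$params)
})

test_that("a noise-free planted path signal is recovered almost perfectly", {
  # trained to convergence: with zero label noise the planted rule is fully
  # recoverable, so validation F1 should approach 1
  cfg <- small_experiment_config(
    seed = 6,
    synth = list(noise_rate = 0),
    train = list(max_epochs = 20L, patience = 20L, n_seeds = 1L))
  res <- run_experiment(cfg, quiet = TRUE)
  expect_gte(res$metrics$val_f1, 0.95)
})
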