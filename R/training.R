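# Training protocol: multiclass cross-entropy minimized with Adam
# (learning rate 0.001), mini-batches of 8, dropout on the combined feature,
# early stopping on validation micro-F1 with best-epoch weight restoration,
# and selection over multiple random initializations.

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param batch_size gradient accumulation size.
#' @param max_epochs epoch cap.
#' @param patience early stopping: epochs without validation-F1 improvement
#'   before training halts (best-epoch weights are restored either way).
#' @param seeds integer seeds for [multi_seed_select()]; one model is
#'   trained per seed and the best validation F1 wins.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer (published
#'   defaults).
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.001, batch_size = 8L, max_epochs = 20L,
                         patience = 3L, seeds = 1:10,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(batch_size >= 1L, length(seeds) >= 1L, max_epochs >= 1L)
  structure(list(lr = lr, batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, seeds = as.integer(seeds),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  corr1 <- 1 - cfg$beta1^state$t
  corr2 <- 1 - cfg$beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- cfg$beta1 * state$m[[k]] + (1 - cfg$beta1) * g
    state$v[[k]] <- cfg$beta2 * state$v[[k]] + (1 - cfg$beta2) * g^2
    params[[k]] <- params[[k]] -
      cfg$lr * (state$m[[k]] / corr1) / (sqrt(state$v[[k]] / corr2) + cfg$eps)
  }
  list(params = params, state = state)
}

add_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (k in names(g)) acc[[k]] <- acc[[k]] + g[[k]]
  acc
}

# Embedding padding rows (row 1) are frozen: their gradients are zeroed
# before every optimizer step.
freeze_pad_rows <- function(grads) {
  for (k in grep("^emb_", names(grads), value = TRUE)) grads[[k]][1L, ] <- 0
  grads
}

#' Micro-averaged F1 over instance label predictions
#'
#' Pools true/false positives and false negatives over all non-"none"
#' categories.
#'
#' @param pred,gold category label vectors (the reserved label `"none"`
#'   counts as no prediction / no gold relation).
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1` (0-1
#'   scale).
#' @export
instance_micro_f1 <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  tp <- sum(pred != "none" & pred == gold)
  fp <- sum(pred != "none" & pred != gold)
  fn <- sum(gold != "none" & pred != gold)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1)
}

#' Train a model from one random initialization
#'
#' Minimizes multiclass cross-entropy with Adam, evaluates micro-F1 on the
#' validation split after every epoch, stops early when the validation F1
#' has not improved for `patience` epochs, and restores the best epoch's
#' weights. Fully reproducible given `seed` (initialization, batch order and
#' dropout all flow from it).
#'
#' @param train_enc,val_enc lists of encoded instances
#'   ([encode_instance()]); validation must contain at least one positive.
#' @param vocab,tables from [build_vocabulary()].
#' @param categories ordered label set including `"none"`.
#' @param mconfig a [model_config()].
#' @param tconfig a [train_config()].
#' @param seed integer seed.
#' @param quiet suppress per-epoch messages.
#' @return a `relx_model` with `history` (per-epoch data.frame: `epoch`,
#'   `loss`, `val_precision`, `val_recall`, `val_f1`), `selected_epoch`
#'   (the argmax of validation F1) and `val_f1`.
#' @export
train_one <- function(train_enc, val_enc, vocab, tables, categories,
                      mconfig = model_config(), tconfig = train_config(),
                      seed = 1L, quiet = TRUE) {
  if (!length(train_enc) || !length(val_enc))
    stopf("empty training or validation split")
  val_gold <- categories[vapply(val_enc, `[[`, integer(1), "label_idx")]
  if (all(val_gold == "none"))
    stopf("validation split has no positive instance; F1 is degenerate")
  model <- model_init(vocab, tables, categories, mconfig, seed)
  withr::with_seed(seed + 1L, {
    state <- adam_init(model$params)
    best <- list(f1 = -Inf, params = model$params, epoch = 0L)
    history <- data.frame()
    stall <- 0L
    for (epoch in seq_len(tconfig$max_epochs)) {
      idx <- sample(seq_along(train_enc))
      total_loss <- 0
      acc <- NULL; in_batch <- 0L
      for (i in idx) {
        enc <- train_enc[[i]]
        fwd <- forward(model, enc, train = TRUE)
        total_loss <- total_loss - log(max(fwd$probs[enc$label_idx], 1e-12))
        acc <- add_grads(acc, backward(model, fwd$cache, enc$label_idx))
        in_batch <- in_batch + 1L
        if (in_batch == tconfig$batch_size) {
          grads <- freeze_pad_rows(lapply(acc, function(g) g / in_batch))
          upd <- adam_step(model$params, grads, state, tconfig)
          model$params <- upd$params; state <- upd$state
          acc <- NULL; in_batch <- 0L
        }
      }
      if (in_batch > 0L) {
        grads <- freeze_pad_rows(lapply(acc, function(g) g / in_batch))
        upd <- adam_step(model$params, grads, state, tconfig)
        model$params <- upd$params; state <- upd$state
      }
      pred <- attr(predict(model, val_enc), "label")
      m <- instance_micro_f1(pred, val_gold)
      history <- rbind(history, data.frame(
        epoch = epoch, loss = total_loss / length(train_enc),
        val_precision = m$precision, val_recall = m$recall, val_f1 = m$f1))
      if (!quiet)
        message(sprintf("epoch %d: loss %.4f val F1 %.4f", epoch,
                        total_loss / length(train_enc), m$f1))
      if (m$f1 > best$f1) {
        best <- list(f1 = m$f1, params = model$params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tconfig$patience) break
      }
    }
    model$params <- best$params
    model$history <- history
    model$selected_epoch <- best$epoch
    model$val_f1 <- best$f1
    model$seed <- seed
  })
  model
}

#' Train under several random initializations and keep the best
#'
#' Trains one model per seed in `tconfig$seeds` and returns the model with
#' the highest validation F1, together with the min/max/mean/SD summary of
#' the per-seed validation F1 scores.
#'
#' @inheritParams train_one
#' @return the selected `relx_model`, with `seed_summary` (list: `f1_by_seed`,
#'   `min`, `max`, `mean`, `sd`) attached.
#' @export
multi_seed_select <- function(train_enc, val_enc, vocab, tables, categories,
                              mconfig = model_config(),
                              tconfig = train_config(), quiet = TRUE) {
  models <- lapply(tconfig$seeds, function(s) {
    if (!quiet) message(sprintf("training seed %d ...", s))
    train_one(train_enc, val_enc, vocab, tables, categories, mconfig,
              tconfig, seed = s, quiet = quiet)
  })
  f1s <- vapply(models, `[[`, numeric(1), "val_f1")
  best <- models[[which.max(f1s)]]
  best$seed_summary <- list(
    f1_by_seed = stats::setNames(f1s, tconfig$seeds),
    min = min(f1s), max = max(f1s), mean = mean(f1s),
    sd = if (length(f1s) > 1L) stats::sd(f1s) else 0)
  best
}
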