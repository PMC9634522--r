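# The relation classifier: a sentence-level encoder over the distributed
# feature combination, joined with an encoder of the shortest dependency
# path, followed by dropout and a softmax output layer.

#' Model configuration
#'
#' @param dims a [feature_dims()] (embedding dimensions).
#' @param encoder sentence-level encoder: `"mha"` (multi-head self-attention,
#'   the default), `"cnn"`, `"bilstm"`, `"cnn_attention"` or
#'   `"bilstm_attention"` (the last two replace max-pooling with additive
#'   attention pooling). All encoders consume the same feature combination,
#'   including the positional encoding.
#' @param heads attention head count; `dims$d_token` must be divisible by it.
#' @param d_k attention scaling dimension; default `d_token / heads` (the
#'   per-head dimension).
#' @param ffn_hidden feed-forward hidden width of the attention block;
#'   default `d_token`.
#' @param sent_filters,sent_windows convolutional sentence-encoder filters
#'   per window and window sizes.
#' @param sent_hidden per-direction hidden size of the BiLSTM sentence
#'   encoder.
#' @param sdp_encoder shortest-dependency-path encoder: `"cnn"` (multi-filter
#'   convolution + max-over-time, the default), `"lstm"` (bidirectional,
#'   final states) or `"none"` (the classifier then consumes the sentence
#'   feature only).
#' @param sdp_filters,sdp_windows SDP convolution filters per window and
#'   window sizes (defaults 128 and 2, 3, 4: output width 384).
#' @param sdp_hidden per-direction hidden size of the recurrent SDP encoder.
#' @param dropout dropout rate applied to the combined feature vector before
#'   the softmax layer (training only).
#' @param pe add the sinusoidal positional encoding to the word channel.
#' @return a `model_config` list with derived output widths.
#' @export
model_config <- function(dims = feature_dims(),
                         encoder = c("mha", "cnn", "bilstm",
                                     "cnn_attention", "bilstm_attention"),
                         heads = 8L, d_k = NULL, ffn_hidden = NULL,
                         sent_filters = 128L, sent_windows = c(2L, 3L, 4L),
                         sent_hidden = 128L,
                         sdp_encoder = c("cnn", "lstm", "none"),
                         sdp_filters = 128L, sdp_windows = c(2L, 3L, 4L),
                         sdp_hidden = 128L,
                         dropout = 0.5, pe = TRUE) {
  encoder <- match.arg(encoder)
  sdp_encoder <- match.arg(sdp_encoder)
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  if (encoder == "mha" && dims$d_token %% heads != 0L)
    stopf("token dimension %d not divisible by %d attention heads",
          dims$d_token, heads)
  sent_dim <- switch(encoder,
    mha = dims$d_token,
    cnn = , cnn_attention = length(sent_windows) * sent_filters,
    bilstm = , bilstm_attention = 2L * sent_hidden)
  sdp_dim <- switch(sdp_encoder,
    cnn = length(sdp_windows) * sdp_filters,
    lstm = 2L * sdp_hidden,
    none = 0L)
  structure(
    list(dims = dims, encoder = encoder, heads = heads,
         d_k = d_k %||% dims$d_token %/% heads,
         ffn_hidden = ffn_hidden %||% dims$d_token,
         sent_filters = sent_filters, sent_windows = sent_windows,
         sent_hidden = sent_hidden,
         sdp_encoder = sdp_encoder, sdp_filters = sdp_filters,
         sdp_windows = sdp_windows, sdp_hidden = sdp_hidden,
         dropout = dropout, pe = pe,
         sent_dim = sent_dim, sdp_dim = sdp_dim),
    class = "model_config"
  )
}

#' Initialize model parameters
#'
#' Embedding tables are copied from [build_vocabulary()] (pretrained rows
#' included); encoder and output weights are drawn under `seed`.
#'
#' @param vocab,tables from [build_vocabulary()].
#' @param categories ordered category labels including `"none"`.
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return a `relx_model` with elements `params`, `config`, `vocab`,
#'   `categories`.
#' @export
model_init <- function(vocab, tables, categories, config = model_config(),
                       seed = 1L) {
  d <- config$dims$d_token
  params <- withr::with_seed(seed, {
    p <- list(emb_word = tables$word, emb_pos = tables$pos,
              emb_etype = tables$etype, emb_dist = tables$dist,
              emb_deptype = tables$deptype)
    p <- c(p, switch(config$encoder,
      mha = mha_init(d, config$heads, config$ffn_hidden),
      cnn = conv_init("sent_conv", d, config$sent_filters, config$sent_windows),
      cnn_attention = c(
        conv_init("sent_conv", d, config$sent_filters, config$sent_windows),
        attnpool_init("sent_pool", config$sent_dim)),
      bilstm = c(lstm_init("sent_lstm_f", d, config$sent_hidden),
                 lstm_init("sent_lstm_b", d, config$sent_hidden)),
      bilstm_attention = c(
        lstm_init("sent_lstm_f", d, config$sent_hidden),
        lstm_init("sent_lstm_b", d, config$sent_hidden),
        attnpool_init("sent_pool", config$sent_dim))))
    p <- c(p, switch(config$sdp_encoder,
      cnn = conv_init("sdp_conv", config$dims$d_sdp, config$sdp_filters,
                      config$sdp_windows),
      lstm = c(lstm_init("sdp_lstm_f", config$dims$d_sdp, config$sdp_hidden),
               lstm_init("sdp_lstm_b", config$dims$d_sdp, config$sdp_hidden)),
      none = list()))
    p$out_W <- xavier(config$sent_dim + config$sdp_dim, length(categories))
    p$out_b <- matrix(0, 1, length(categories))
    p
  })
  structure(list(params = params, config = config, vocab = vocab,
                 categories = categories),
            class = "relx_model")
}

#' @export
print.relx_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<relx_model: %s encoder + %s SDP encoder, %d categories, %s parameters>\n",
              x$config$encoder, x$config$sdp_encoder, length(x$categories),
              format(np, big.mark = ",")))
  invisible(x)
}

param_tables <- function(params) {
  list(word = params$emb_word, pos = params$emb_pos, etype = params$emb_etype,
       dist = params$emb_dist, deptype = params$emb_deptype)
}

#' Encode a sentence feature matrix to one vector
#'
#' The multi-head attention sentence encoder: multi-head self-attention, a
#' position-wise feed-forward layer, a residual connection around the block,
#' then column-wise max-pooling over the tokens.
#'
#' @param X `n x d` feature-combination matrix.
#' @param params parameter list holding the attention and feed-forward
#'   weights (see [mha_init] via [model_init()]).
#' @param heads head count.
#' @param d_k attention scaling dimension (default `d / heads`).
#' @return a length-`d` sentence vector.
#' @export
encode_sentence <- function(X, params, heads = 8L, d_k = NULL) {
  fwd <- mha_block_forward(X, params, heads, d_k)
  pool_max_forward(fwd$H)$out
}

#' Encode a shortest-dependency-path matrix to one vector
#'
#' @param P `L x d_sdp` path matrix (zero-padded so every window fits, see
#'   [instance_features()]).
#' @param params parameter list holding the SDP convolution weights.
#' @param config a [model_config()] with `sdp_encoder = "cnn"` or `"lstm"`;
#'   with `"none"` a zero-length vector is returned.
#' @return the SDP feature vector (width `config$sdp_dim`).
#' @export
encode_sdp <- function(P, params, config) {
  sdp_forward(P, params, config)$out
}

sent_forward <- function(X, params, cfg) {
  if (cfg$encoder == "mha") {
    blk <- mha_block_forward(X, params, cfg$heads, cfg$d_k)
    H <- blk$H; enc_cache <- blk$cache
  } else if (cfg$encoder %in% c("cnn", "cnn_attention")) {
    cv <- conv_forward(X, params, "sent_conv", cfg$sent_filters,
                       cfg$sent_windows, same = TRUE)
    H <- do.call(cbind, cv$outs)
    enc_cache <- cv
  } else {
    bl <- bilstm_forward(X, params, "sent_lstm", cfg$sent_hidden)
    H <- bl$H; enc_cache <- bl
  }
  if (cfg$encoder %in% c("cnn_attention", "bilstm_attention")) {
    ap <- attnpool_forward(H, params, "sent_pool")
    list(out = ap$out, H = H, enc_cache = enc_cache, pool = ap$cache,
         pooling = "attn")
  } else {
    mp <- pool_max_forward(H)
    list(out = mp$out, H = H, enc_cache = enc_cache, pool = mp,
         pooling = "max")
  }
}

sent_backward <- function(X, params, cfg, cache, dout) {
  dH <- if (cache$pooling == "attn") {
    ab <- attnpool_backward(cache$H, params, "sent_pool", cache$pool, dout)
    pool_grads <- ab$grads
    ab$dH
  } else {
    pool_grads <- list()
    pool_max_backward(cache$pool, nrow(cache$H), dout)
  }
  if (cfg$encoder == "mha") {
    bk <- mha_block_backward(cache$enc_cache, params, dH)
  } else if (cfg$encoder %in% c("cnn", "cnn_attention")) {
    nf <- cfg$sent_filters
    douts <- list()
    for (k in seq_along(cfg$sent_windows)) {
      w <- cfg$sent_windows[k]
      douts[[as.character(w)]] <- dH[, ((k - 1L) * nf + 1L):(k * nf), drop = FALSE]
    }
    bk <- conv_backward(X, params, "sent_conv", cfg$sent_windows,
                        cache$enc_cache$caches, douts)
  } else {
    bk <- bilstm_backward(X, params, "sent_lstm", cfg$sent_hidden,
                          cache$enc_cache, dH)
  }
  list(dX = bk$dX, grads = c(bk$grads, pool_grads))
}

sdp_forward <- function(P, params, cfg) {
  if (cfg$sdp_encoder == "none") return(list(out = numeric(0)))
  if (is.null(P)) return(list(out = rep(0, cfg$sdp_dim), absent = TRUE))
  if (cfg$sdp_encoder == "cnn") {
    cv <- conv_forward(P, params, "sdp_conv", cfg$sdp_filters,
                       cfg$sdp_windows, same = FALSE)
    pooled <- list(); args <- list()
    for (w in cfg$sdp_windows) {
      mp <- pool_max_forward(cv$outs[[as.character(w)]])
      pooled[[as.character(w)]] <- mp$out
      args[[as.character(w)]] <- mp
    }
    list(out = unlist(pooled, use.names = FALSE), conv = cv, pools = args)
  } else {
    fw <- lstm_forward(P, params, "sdp_lstm_f", cfg$sdp_hidden)
    rev_idx <- rev(seq_len(nrow(P)))
    bw <- lstm_forward(P[rev_idx, , drop = FALSE], params, "sdp_lstm_b",
                       cfg$sdp_hidden)
    list(out = c(fw$H[nrow(P), ], bw$H[nrow(P), ]), fw = fw, bw = bw)
  }
}

sdp_backward <- function(P, params, cfg, cache, dout) {
  if (cfg$sdp_encoder == "none" || isTRUE(cache$absent))
    return(list(dP = NULL, grads = list()))
  if (cfg$sdp_encoder == "cnn") {
    douts <- list()
    off <- 0L
    for (w in cfg$sdp_windows) {
      key <- as.character(w)
      nf <- cfg$sdp_filters
      dpool <- dout[(off + 1L):(off + nf)]
      off <- off + nf
      douts[[key]] <- pool_max_backward(cache$pools[[key]],
                                        nrow(cache$conv$outs[[key]]), dpool)
    }
    bk <- conv_backward(P, params, "sdp_conv", cfg$sdp_windows,
                        cache$conv$caches, douts)
    list(dP = bk$dX, grads = bk$grads)
  } else {
    h <- cfg$sdp_hidden
    Tn <- nrow(P)
    rev_idx <- rev(seq_len(Tn))
    dHf <- matrix(0, Tn, h); dHf[Tn, ] <- dout[1:h]
    dHb <- matrix(0, Tn, h); dHb[Tn, ] <- dout[h + 1:h]
    bf <- lstm_backward(P, params, "sdp_lstm_f", h, cache$fw$cache, dHf)
    bb <- lstm_backward(P[rev_idx, , drop = FALSE], params, "sdp_lstm_b", h,
                        cache$bw$cache, dHb)
    list(dP = bf$dX + bb$dX[rev_idx, , drop = FALSE],
         grads = c(bf$grads, bb$grads))
  }
}

#' Forward pass for one encoded instance
#'
#' @param model a `relx_model`.
#' @param enc an [encode_instance()] result.
#' @param train apply dropout (training mode). In evaluation mode the
#'   forward pass is deterministic.
#' @return list with `probs` (per-category probability row summing to 1)
#'   and, invisibly for training, the full `cache`.
#' @export
forward <- function(model, enc, train = FALSE) {
  cfg <- model$config
  params <- model$params
  feats <- instance_features(enc, param_tables(params), pe = cfg$pe,
                             pad_to = max(cfg$sdp_windows))
  sf <- sent_forward(feats$X, params, cfg)
  pf <- sdp_forward(feats$P, params, cfg)
  z <- c(sf$out, pf$out)
  mask <- rep(1, length(z))
  if (train && cfg$dropout > 0) {
    mask <- (stats::runif(length(z)) >= cfg$dropout) / (1 - cfg$dropout)
  }
  zd <- z * mask
  logits <- as.vector(zd %*% params$out_W) + as.vector(params$out_b)
  probs <- softmax_vec(logits)
  list(probs = probs,
       cache = list(feats = feats, sf = sf, pf = pf, z = z, zd = zd,
                    mask = mask, probs = probs, enc = enc))
}

# Cross-entropy backward for one instance; returns the named gradient list.
backward <- function(model, cache, label_idx) {
  cfg <- model$config
  params <- model$params
  dlogits <- cache$probs
  dlogits[label_idx] <- dlogits[label_idx] - 1
  g <- list()
  g$out_W <- cache$zd %o% dlogits
  g$out_b <- matrix(dlogits, 1)
  dz <- as.vector(params$out_W %*% dlogits) * cache$mask
  ns <- cfg$sent_dim
  sb <- sent_backward(cache$feats$X, params, cfg, cache$sf, dz[seq_len(ns)])
  g <- c(g, sb$grads)
  if (cfg$sdp_dim > 0L) {
    pb <- sdp_backward(cache$feats$P, params, cfg, cache$pf, dz[ns + seq_len(cfg$sdp_dim)])
    g <- c(g, pb$grads)
  } else pb <- list(dP = NULL)
  c(g, embedding_grads(model, cache, sb$dX, pb$dP))
}

embedding_grads <- function(model, cache, dX, dP) {
  dims <- model$config$dims
  enc <- cache$enc
  g <- list(emb_word = model$params$emb_word * 0,
            emb_pos = model$params$emb_pos * 0,
            emb_etype = model$params$emb_etype * 0,
            emb_dist = model$params$emb_dist * 0,
            emb_deptype = model$params$emb_deptype * 0)
  cw <- seq_len(dims$word)
  cp <- dims$word + seq_len(dims$pos)
  ce <- dims$word + dims$pos + seq_len(dims$etype)
  c1 <- dims$word + dims$pos + dims$etype + seq_len(dims$dist)
  c2 <- dims$word + dims$pos + dims$etype + dims$dist + seq_len(dims$dist)
  for (t in seq_len(enc$n)) {
    g$emb_word[enc$word_idx[t], ] <- g$emb_word[enc$word_idx[t], ] + dX[t, cw]
    g$emb_pos[enc$pos_idx[t], ] <- g$emb_pos[enc$pos_idx[t], ] + dX[t, cp]
    g$emb_etype[enc$etype_idx[t], ] <- g$emb_etype[enc$etype_idx[t], ] + dX[t, ce]
    g$emb_dist[enc$dist1_idx[t], ] <- g$emb_dist[enc$dist1_idx[t], ] + dX[t, c1]
    g$emb_dist[enc$dist2_idx[t], ] <- g$emb_dist[enc$dist2_idx[t], ] + dX[t, c2]
  }
  if (!is.null(dP)) {
    sw <- seq_len(dims$word)
    sd <- dims$word + seq_len(dims$deptype)
    widx <- cache$feats$sdp_widx
    didx <- cache$feats$sdp_didx
    for (t in seq_len(nrow(dP))) {
      g$emb_word[widx[t], ] <- g$emb_word[widx[t], ] + dP[t, sw]
      g$emb_deptype[didx[t], ] <- g$emb_deptype[didx[t], ] + dP[t, sd]
    }
  }
  g
}

#' Predict relation probabilities for encoded instances
#'
#' @param object a `relx_model`.
#' @param newdata list of encoded instances.
#' @param ... unused.
#' @return matrix of per-category probabilities (one row per instance) with
#'   the category names as columns; attribute `"label"` holds the argmax
#'   category per instance.
#' @export
predict.relx_model <- function(object, newdata, ...) {
  probs <- t(vapply(newdata, function(enc) forward(object, enc)$probs,
                    numeric(length(object$categories))))
  colnames(probs) <- object$categories
  attr(probs, "label") <- object$categories[max.col(probs, ties.method = "first")]
  probs
}
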