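# Neural encoder primitives: forward passes with caches, and backward passes
# returning input and parameter gradients. All are plain matrix code; every
# backward is covered by finite-difference gradient checks in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

xavier <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

## ---- scaled dot-product attention -------------------------------------

#' Scaled dot-product attention
#'
#' `weights = softmax(Q K' / sqrt(d_k))` row-wise; `context = weights V`.
#' Every weight row is non-negative and sums to one.
#'
#' @param Q,K,V `n x d_head` matrices (queries, keys, values).
#' @param d_k scaling dimension (the per-head dimension by default).
#' @return list with `context` (`n x d_head`) and `weights` (`n x n`).
#' @export
scaled_dot_product_attention <- function(Q, K, V, d_k = ncol(K)) {
  if (!all(is.finite(Q), is.finite(K), is.finite(V)))
    stopf("non-finite attention inputs")
  S <- (Q %*% t(K)) / sqrt(d_k)
  A <- softmax_rows(S)
  list(context = A %*% V, weights = A)
}

# backward through context = softmax(QK'/sqrt(dk)) V
sdpa_backward <- function(Q, K, V, A, d_k, dC) {
  dA <- dC %*% t(V)
  dV <- t(A) %*% dC
  dS <- A * (dA - rowSums(dA * A))
  dQ <- (dS %*% K) / sqrt(d_k)
  dK <- (t(dS) %*% Q) / sqrt(d_k)
  list(dQ = dQ, dK = dK, dV = dV)
}

## ---- multi-head attention block ---------------------------------------

mha_init <- function(d, heads, ffn_hidden) {
  dh <- d %/% heads
  p <- list()
  for (h in seq_len(heads)) {
    p[[paste0("Wq", h)]] <- xavier(d, dh)
    p[[paste0("Wk", h)]] <- xavier(d, dh)
    p[[paste0("Wv", h)]] <- xavier(d, dh)
  }
  p$ffn_W1 <- xavier(d, ffn_hidden)
  p$ffn_b1 <- matrix(0, 1, ffn_hidden)
  p$ffn_W2 <- xavier(ffn_hidden, d)
  p$ffn_b2 <- matrix(0, 1, d)
  p
}

#' Multi-head self-attention
#'
#' Eight (by default) scaled dot-product attention heads with unshared
#' projection weights; per-head outputs are concatenated along the feature
#' axis, so the output width equals the input width `d`.
#'
#' @param X `n x d` feature-combination matrix.
#' @param params named parameter list holding `Wq<i>`, `Wk<i>`, `Wv<i>`.
#' @param heads number of heads; `d` must be divisible by `heads`.
#' @param d_k scaling dimension; defaults to the per-head dimension `d/heads`.
#' @return `n x d` matrix of concatenated head outputs.
#' @export
multi_head <- function(X, params, heads = 8L, d_k = NULL) {
  mha_core(X, params, heads, d_k)$M
}

mha_core <- function(X, params, heads, d_k = NULL) {
  d <- ncol(X)
  if (d %% heads != 0L) stopf("model dimension %d not divisible by %d heads", d, heads)
  dh <- d %/% heads
  if (is.null(d_k)) d_k <- dh
  caches <- vector("list", heads)
  M <- matrix(0, nrow(X), d)
  for (h in seq_len(heads)) {
    Q <- X %*% params[[paste0("Wq", h)]]
    K <- X %*% params[[paste0("Wk", h)]]
    V <- X %*% params[[paste0("Wv", h)]]
    att <- scaled_dot_product_attention(Q, K, V, d_k)
    M[, ((h - 1L) * dh + 1L):(h * dh)] <- att$context
    caches[[h]] <- list(Q = Q, K = K, V = V, A = att$weights)
  }
  list(M = M, caches = caches, dh = dh, d_k = d_k)
}

mha_block_forward <- function(X, params, heads, d_k = NULL) {
  core <- mha_core(X, params, heads, d_k)
  Z1 <- core$M %*% params$ffn_W1 + matrix(params$ffn_b1, nrow(X), ncol(params$ffn_W1), byrow = TRUE)
  H1 <- pmax(Z1, 0)
  FF <- H1 %*% params$ffn_W2 + matrix(params$ffn_b2, nrow(X), ncol(params$ffn_W2), byrow = TRUE)
  Y <- FF + X  # residual around the attention + feed-forward block
  list(H = Y, cache = list(X = X, core = core, Z1 = Z1, H1 = H1, heads = heads))
}

mha_block_backward <- function(cache, params, dY) {
  X <- cache$X; core <- cache$core
  g <- list()
  dFF <- dY
  dX <- dY  # residual path
  g$ffn_W2 <- t(cache$H1) %*% dFF
  g$ffn_b2 <- matrix(colSums(dFF), 1)
  dH1 <- dFF %*% t(params$ffn_W2)
  dZ1 <- dH1 * (cache$Z1 > 0)
  g$ffn_W1 <- t(core$M) %*% dZ1
  g$ffn_b1 <- matrix(colSums(dZ1), 1)
  dM <- dZ1 %*% t(params$ffn_W1)
  dh <- core$dh
  for (h in seq_len(cache$heads)) {
    cc <- core$caches[[h]]
    dC <- dM[, ((h - 1L) * dh + 1L):(h * dh), drop = FALSE]
    bk <- sdpa_backward(cc$Q, cc$K, cc$V, cc$A, core$d_k, dC)
    g[[paste0("Wq", h)]] <- t(X) %*% bk$dQ
    g[[paste0("Wk", h)]] <- t(X) %*% bk$dK
    g[[paste0("Wv", h)]] <- t(X) %*% bk$dV
    dX <- dX + bk$dQ %*% t(params[[paste0("Wq", h)]]) +
               bk$dK %*% t(params[[paste0("Wk", h)]]) +
               bk$dV %*% t(params[[paste0("Wv", h)]])
  }
  list(dX = dX, grads = g)
}

## ---- convolution ------------------------------------------------------

# Rows of the window matrix are flattened length-w input windows.
conv_windows <- function(X, w, same = FALSE) {
  if (same) {
    top <- (w - 1L) %/% 2L
    bot <- w - 1L - top
    X <- rbind(matrix(0, top, ncol(X)), X, matrix(0, bot, ncol(X)))
  }
  npos <- nrow(X) - w + 1L
  idx <- outer(seq_len(npos), seq_len(w) - 1L, `+`)
  W <- matrix(0, npos, w * ncol(X))
  for (k in seq_len(w)) {
    W[, ((k - 1L) * ncol(X) + 1L):(k * ncol(X))] <- X[idx[, k], , drop = FALSE]
  }
  list(W = W, idx = idx, pad_top = if (same) (w - 1L) %/% 2L else 0L)
}

conv_scatter <- function(dWin, idx, n, d, pad_top) {
  dX <- matrix(0, n, d)
  w <- ncol(idx)
  for (k in seq_len(w)) {
    rows <- idx[, k] - pad_top
    ok <- rows >= 1L & rows <= n
    if (any(ok)) {
      block <- dWin[ok, ((k - 1L) * d + 1L):(k * d), drop = FALSE]
      for (r in seq_len(sum(ok))) {
        dX[rows[ok][r], ] <- dX[rows[ok][r], ] + block[r, ]
      }
    }
  }
  dX
}

conv_init <- function(prefix, d_in, filters, windows) {
  p <- list()
  for (w in windows) {
    p[[paste0(prefix, "_W", w)]] <- xavier(w * d_in, filters)
    p[[paste0(prefix, "_b", w)]] <- matrix(0, 1, filters)
  }
  p
}

# Multi-filter convolution, ReLU. same = TRUE keeps one output position per
# input row (sentence encoder); same = FALSE uses valid positions (SDP
# encoder, input pre-padded so every window fits).
conv_forward <- function(X, params, prefix, filters, windows, same) {
  outs <- list(); caches <- list()
  for (w in windows) {
    cw <- conv_windows(X, w, same)
    Z <- cw$W %*% params[[paste0(prefix, "_W", w)]] +
      matrix(params[[paste0(prefix, "_b", w)]], nrow(cw$W), filters, byrow = TRUE)
    R <- pmax(Z, 0)
    outs[[as.character(w)]] <- R
    caches[[as.character(w)]] <- list(win = cw, Z = Z)
  }
  list(outs = outs, caches = caches)
}

conv_backward <- function(X, params, prefix, windows, caches, douts) {
  g <- list()
  dX <- matrix(0, nrow(X), ncol(X))
  for (w in windows) {
    key <- as.character(w)
    cc <- caches[[key]]
    dZ <- douts[[key]] * (cc$Z > 0)
    g[[paste0(prefix, "_W", w)]] <- t(cc$win$W) %*% dZ
    g[[paste0(prefix, "_b", w)]] <- matrix(colSums(dZ), 1)
    dWin <- dZ %*% t(params[[paste0(prefix, "_W", w)]])
    dX <- dX + conv_scatter(dWin, cc$win$idx, nrow(X), ncol(X), cc$win$pad_top)
  }
  list(dX = dX, grads = g)
}

## ---- LSTM -------------------------------------------------------------

lstm_init <- function(prefix, d_in, hidden) {
  p <- list()
  p[[paste0(prefix, "_W")]] <- xavier(d_in, 4L * hidden)
  p[[paste0(prefix, "_U")]] <- xavier(hidden, 4L * hidden)
  p[[paste0(prefix, "_b")]] <- matrix(0, 1, 4L * hidden)
  p
}

lstm_forward <- function(X, params, prefix, hidden) {
  Tn <- nrow(X)
  W <- params[[paste0(prefix, "_W")]]
  U <- params[[paste0(prefix, "_U")]]
  b <- params[[paste0(prefix, "_b")]]
  H <- matrix(0, Tn, hidden)
  h_prev <- matrix(0, 1, hidden); c_prev <- matrix(0, 1, hidden)
  cache <- vector("list", Tn)
  gi <- 1:hidden; gf <- hidden + gi; gg <- 2L * hidden + gi; go <- 3L * hidden + gi
  for (t in seq_len(Tn)) {
    a <- X[t, , drop = FALSE] %*% W + h_prev %*% U + b
    i <- sigmoid(a[, gi, drop = FALSE]); f <- sigmoid(a[, gf, drop = FALSE])
    g <- tanh(a[, gg, drop = FALSE]);    o <- sigmoid(a[, go, drop = FALSE])
    c_t <- f * c_prev + i * g
    tc <- tanh(c_t)
    h_t <- o * tc
    H[t, ] <- h_t
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev,
                       tc = tc, h_prev = h_prev)
    h_prev <- h_t; c_prev <- c_t
  }
  list(H = H, cache = cache)
}

lstm_backward <- function(X, params, prefix, hidden, cache, dH) {
  Tn <- nrow(X)
  W <- params[[paste0(prefix, "_W")]]
  U <- params[[paste0(prefix, "_U")]]
  dW <- W * 0; dU <- U * 0; db <- matrix(0, 1, 4L * hidden)
  dX <- X * 0
  dh_next <- matrix(0, 1, hidden); dc_next <- matrix(0, 1, hidden)
  gi <- 1:hidden; gf <- hidden + gi; gg <- 2L * hidden + gi; go <- 3L * hidden + gi
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dh <- dH[t, , drop = FALSE] + dh_next
    do_ <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g; dg <- dc * cc$i; df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    da <- matrix(0, 1, 4L * hidden)
    da[, gi] <- di * cc$i * (1 - cc$i)
    da[, gf] <- df * cc$f * (1 - cc$f)
    da[, gg] <- dg * (1 - cc$g^2)
    da[, go] <- do_ * cc$o * (1 - cc$o)
    dW <- dW + t(X[t, , drop = FALSE]) %*% da
    dU <- dU + t(cc$h_prev) %*% da
    db <- db + da
    dX[t, ] <- da %*% t(W)
    dh_next <- da %*% t(U)
  }
  g <- list()
  g[[paste0(prefix, "_W")]] <- dW
  g[[paste0(prefix, "_U")]] <- dU
  g[[paste0(prefix, "_b")]] <- db
  list(dX = dX, grads = g)
}

bilstm_forward <- function(X, params, prefix, hidden) {
  fw <- lstm_forward(X, params, paste0(prefix, "_f"), hidden)
  rev_idx <- rev(seq_len(nrow(X)))
  bw <- lstm_forward(X[rev_idx, , drop = FALSE], params, paste0(prefix, "_b"), hidden)
  H <- cbind(fw$H, bw$H[rev_idx, , drop = FALSE])
  list(H = H, fw = fw, bw = bw)
}

bilstm_backward <- function(X, params, prefix, hidden, cache, dH) {
  rev_idx <- rev(seq_len(nrow(X)))
  dHf <- dH[, 1:hidden, drop = FALSE]
  dHb <- dH[, hidden + 1:hidden, drop = FALSE][rev_idx, , drop = FALSE]
  bf <- lstm_backward(X, params, paste0(prefix, "_f"), hidden, cache$fw$cache, dHf)
  bb <- lstm_backward(X[rev_idx, , drop = FALSE], params, paste0(prefix, "_b"),
                      hidden, cache$bw$cache, dHb)
  list(dX = bf$dX + bb$dX[rev_idx, , drop = FALSE], grads = c(bf$grads, bb$grads))
}

## ---- pooling ----------------------------------------------------------

pool_max_forward <- function(H) {
  arg <- max.col(t(H), ties.method = "first")
  list(out = vapply(seq_len(ncol(H)), function(j) H[arg[j], j], numeric(1)),
       arg = arg)
}

pool_max_backward <- function(cache, nrow_H, dout) {
  dH <- matrix(0, nrow_H, length(dout))
  for (j in seq_along(dout)) dH[cache$arg[j], j] <- dout[j]
  dH
}

attnpool_init <- function(prefix, q) {
  p <- list()
  p[[paste0(prefix, "_W")]] <- xavier(q, q)
  p[[paste0(prefix, "_b")]] <- matrix(0, 1, q)
  p[[paste0(prefix, "_v")]] <- xavier(q, 1L)
  p
}

# Additive (single-head, tanh-scored) attention pooling over rows of H.
attnpool_forward <- function(H, params, prefix) {
  W <- params[[paste0(prefix, "_W")]]
  b <- params[[paste0(prefix, "_b")]]
  v <- params[[paste0(prefix, "_v")]]
  U <- tanh(H %*% W + matrix(b, nrow(H), ncol(W), byrow = TRUE))
  s <- as.vector(U %*% v)
  alpha <- softmax_vec(s)
  list(out = as.vector(t(H) %*% alpha), cache = list(U = U, alpha = alpha))
}

attnpool_backward <- function(H, params, prefix, cache, dout) {
  W <- params[[paste0(prefix, "_W")]]
  v <- params[[paste0(prefix, "_v")]]
  alpha <- cache$alpha; U <- cache$U
  dH <- alpha %o% dout
  dalpha <- as.vector(H %*% dout)
  ds <- alpha * (dalpha - sum(dalpha * alpha))
  dv <- t(U) %*% ds
  dU <- ds %o% as.vector(v)
  dpre <- dU * (1 - U^2)
  g <- list()
  g[[paste0(prefix, "_W")]] <- t(H) %*% dpre
  g[[paste0(prefix, "_b")]] <- matrix(colSums(dpre), 1)
  g[[paste0(prefix, "_v")]] <- dv
  list(dH = dH + dpre %*% t(W), grads = g)
}
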