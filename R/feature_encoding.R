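# Distributed feature encoding.
#
# Every token of a candidate sentence is represented as the concatenation
# [word embedding + positional encoding | POS | entity type | distance to
# entity 1 | distance to entity 2]; with the default dimensions
# 200 + 200 + 200 + 100 + 100 this is an 800-dimensional vector per token.
# The shortest-dependency-path channel concatenates [word | dependency type]
# per path token (200 + 200 = 400 by default), the dependency-type sequence
# being one shorter than the token sequence and padded to the path length.

#' Feature dimension configuration
#'
#' @param word,pos,etype,dist,deptype embedding dimensions. The distance
#'   table is shared by both distance chains. Defaults give a per-token
#'   sentence dimension of `word + pos + etype + 2 * dist = 800` and an SDP
#'   channel width of `word + deptype = 400`.
#' @return a named list of dimensions with derived totals `d_token`, `d_sdp`.
#' @export
feature_dims <- function(word = 200L, pos = 200L, etype = 200L,
                         dist = 100L, deptype = 200L) {
  if (word %% 2L != 0L) stopf("word dimension must be even (positional encoding)")
  list(word = word, pos = pos, etype = etype, dist = dist, deptype = deptype,
       d_token = word + pos + etype + 2L * dist,
       d_sdp = word + deptype)
}

PAD_IDX <- 1L
UNK_IDX <- 2L

#' Build vocabulary and embedding tables
#'
#' The word dictionary is the most frequent `k` words — taken from a
#' pretrained embedding table when one is given (word2vec text files are
#' frequency-ordered), otherwise from corpus frequency. One placeholder word
#' per configured entity type is added and randomly initialized: at lookup,
#' an entity token missing from the dictionary is replaced by its type's
#' placeholder. POS, entity-type, dependency-type and distance inventories
#' are collected from the instances. All randomly initialized rows are drawn
#' under `seed`; row 1 of every table is the all-zero padding row and is
#' frozen during training.
#'
#' @param instances list of `candidate_instance` (training split).
#' @param entity_types character vector of entity-type names.
#' @param k dictionary size cap.
#' @param embeddings optional pretrained table from [read_word2vec()].
#' @param dims a [feature_dims()].
#' @param seed integer seed for random initialization.
#' @return list with `vocab` (index maps and the corpus maximum distance
#'   `s_max`) and `tables` (list of embedding matrices `word`, `pos`,
#'   `etype`, `dist`, `deptype`).
#' @export
build_vocabulary <- function(instances, entity_types, k = 100000L,
                             embeddings = NULL, dims = feature_dims(),
                             seed = 1L) {
  stopifnot(k > 0L)
  toks <- unlist(lapply(instances, `[[`, "tokens"))
  if (is.null(embeddings)) {
    freq <- sort(table(toks), decreasing = TRUE)
    words <- utils::head(names(freq), k)
  } else {
    words <- utils::head(rownames(embeddings), k)
  }
  placeholders <- setdiff(entity_types, words)
  word_list <- c("<pad>", "<unk>", placeholders, words)
  pos_list <- c("<pad>", "<unk>", sort(unique(unlist(lapply(instances, `[[`, "pos")))))
  dep_list <- c("<pad>", "<unk>",
                sort(unique(unlist(lapply(instances, function(x) x$sdp$deptype_seq)))))
  etype_list <- c("<pad>", "<none>", entity_types)
  s_max <- max(1L, abs(unlist(lapply(instances, function(x)
    c(x$dist1_seq, x$dist2_seq)))))
  vocab <- list(
    words = word_list, word_index = index_map(word_list),
    placeholder = stats::setNames(match(entity_types, word_list), entity_types),
    pos = pos_list, pos_index = index_map(pos_list),
    deptype = dep_list, deptype_index = index_map(dep_list),
    etype = etype_list, etype_index = index_map(etype_list),
    s_max = s_max, dims = dims
  )
  tables <- withr::with_seed(seed, init_tables(vocab, embeddings, dims))
  list(vocab = vocab, tables = tables)
}

index_map <- function(x) stats::setNames(seq_along(x), x)

rand_table <- function(rows, cols, scale = 0.1) {
  m <- matrix(stats::runif(rows * cols, -scale, scale), rows, cols)
  m[PAD_IDX, ] <- 0
  m
}

init_tables <- function(vocab, embeddings, dims) {
  word <- rand_table(length(vocab$words), dims$word)
  if (!is.null(embeddings)) {
    if (ncol(embeddings) != dims$word)
      stopf("pretrained embedding dimension %d != configured word dimension %d",
            ncol(embeddings), dims$word)
    hit <- intersect(vocab$words, rownames(embeddings))
    word[match(hit, vocab$words), ] <- embeddings[hit, , drop = FALSE]
    word[PAD_IDX, ] <- 0
  }
  list(word = word,
       pos = rand_table(length(vocab$pos), dims$pos),
       etype = rand_table(length(vocab$etype), dims$etype),
       dist = rand_table(2L * vocab$s_max + 2L, dims$dist),
       deptype = rand_table(length(vocab$deptype), dims$deptype))
}

#' Relative distance
#'
#' Signed token distance scaled by the corpus maximum absolute distance:
#' `l / s`, a non-integer value in `[-1, 1]`, monotone in `l`. Distances are
#' bucketized at resolution `1/s` (one embedding row per integer offset) for
#' table lookup.
#'
#' @param l signed token offset, `|l| <= s`.
#' @param s corpus maximum absolute distance, `> 0`.
#' @return `l / s`.
#' @export
relative_distance <- function(l, s) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0) stopf("s must be a positive scalar")
  if (any(abs(l) > s)) stopf("|l| exceeds the maximum distance s = %d", s)
  l / s
}

dist_index <- function(l, s) {
  pmin(pmax(l, -s), s) + s + 2L  # row 1 is PAD; rows 2..(2s+2) cover -s..s
}

#' Sinusoidal positional encoding
#'
#' `PE[pos, 2i] = sin(pos / 10000^(2i/d))`,
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/d))` for dimension pairs
#' `i = 0, ..., d/2 - 1` and positions `pos = 0, ..., n - 1` (row 1 of the
#' returned matrix is position 0). Added element-wise to the word-embedding
#' channel only.
#'
#' @param n sequence length.
#' @param d encoding dimension (even, equal to the word dimension).
#' @return an `n x d` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(n, d) {
  if (d %% 2L != 0L) stopf("positional encoding dimension must be even, got %d", d)
  pos <- seq_len(n) - 1L
  i <- seq_len(d %/% 2L) - 1L
  angle <- outer(pos, 1 / 10000^(2 * i / d))
  pe <- matrix(0, n, d)
  pe[, 2L * i + 1L] <- sin(angle)
  pe[, 2L * i + 2L] <- cos(angle)
  pe
}

#' Encode a candidate instance to index sequences
#'
#' Pure function of (instance, vocabulary): maps tokens, POS tags, entity
#' types, distances and the SDP channel to table indices. Entity tokens
#' absent from the word dictionary map to their entity-type placeholder;
#' other unknown words map to `<unk>`. Distances beyond the corpus maximum
#' are clamped to the extreme buckets.
#'
#' @param inst a `candidate_instance`.
#' @param vocab vocabulary from [build_vocabulary()].
#' @param categories ordered category label set including `"none"` (e.g.
#'   `task$category_names`).
#' @return an `encoded_instance`: index vectors `word_idx`, `pos_idx`,
#'   `etype_idx`, `dist1_idx`, `dist2_idx` (length `n`), relative distances
#'   `rel1`, `rel2` in `[-1, 1]`, `sdp_word_idx` (length `m`),
#'   `sdp_dep_idx` (length `m`, dependency types padded to the path length),
#'   `label_idx`, `n`, `m` and the `intra` flag.
#' @export
encode_instance <- function(inst, vocab, categories) {
  n <- length(inst$tokens)
  widx <- lookup_words(inst$tokens, inst$entity_type_seq, vocab)
  pidx <- lookup(inst$pos, vocab$pos_index)
  eidx <- lookup(ifelse(is.na(inst$entity_type_seq), "<none>", inst$entity_type_seq),
                 vocab$etype_index)
  s <- vocab$s_max
  lab <- match(inst$label, categories)
  if (is.na(lab)) stopf("label '%s' not in the task category set", inst$label)
  enc <- list(
    word_idx = widx, pos_idx = pidx, etype_idx = eidx,
    dist1_idx = dist_index(inst$dist1_seq, s),
    dist2_idx = dist_index(inst$dist2_seq, s),
    rel1 = relative_distance(pmin(pmax(inst$dist1_seq, -s), s), s),
    rel2 = relative_distance(pmin(pmax(inst$dist2_seq, -s), s), s),
    label_idx = lab, n = n, intra = inst$intra %||% TRUE
  )
  if (!is.null(inst$sdp)) {
    m <- inst$sdp$m
    sdp_types <- inst$sdp$deptype_seq
    ent_types <- rep(NA_character_, m)  # path endpoints are entities
    ent_types[c(1L, m)] <- c(inst$e1_type, inst$e2_type)
    enc$sdp_word_idx <- lookup_words(inst$sdp$words, ent_types, vocab)
    enc$sdp_dep_idx <- c(lookup(sdp_types, vocab$deptype_index),
                         rep(PAD_IDX, m - length(sdp_types)))
    enc$m <- m
  } else {
    enc$sdp_word_idx <- integer()
    enc$sdp_dep_idx <- integer()
    enc$m <- 0L
  }
  structure(enc, class = "encoded_instance")
}

lookup <- function(x, map) {
  i <- unname(map[x])
  i[is.na(i)] <- UNK_IDX
  i
}

lookup_words <- function(words, ent_types, vocab) {
  i <- unname(vocab$word_index[words])
  miss <- which(is.na(i))
  for (j in miss) {
    i[j] <- if (!is.na(ent_types[j]) && ent_types[j] %in% names(vocab$placeholder))
      vocab$placeholder[[ent_types[j]]] else UNK_IDX
  }
  i
}

#' Materialize the feature matrices of an encoded instance
#'
#' @param enc an [encode_instance()] result.
#' @param tables embedding tables from [build_vocabulary()].
#' @param pe add the sinusoidal positional encoding to the word channel
#'   (default `TRUE`).
#' @param pad_to minimum SDP matrix length (pad with zero rows so every
#'   convolution window fits).
#' @return list with `X` (`n x d_token` sentence matrix) and `P`
#'   (`max(m, pad_to) x d_sdp` SDP matrix, zero-padded; `NULL` when the
#'   instance has no path).
#' @export
instance_features <- function(enc, tables, pe = TRUE, pad_to = 1L) {
  W <- tables$word[enc$word_idx, , drop = FALSE]
  if (pe) W <- W + positional_encoding(enc$n, ncol(tables$word))
  X <- cbind(W,
             tables$pos[enc$pos_idx, , drop = FALSE],
             tables$etype[enc$etype_idx, , drop = FALSE],
             tables$dist[enc$dist1_idx, , drop = FALSE],
             tables$dist[enc$dist2_idx, , drop = FALSE])
  P <- NULL
  if (enc$m > 0L) {
    L <- max(enc$m, pad_to)
    widx <- c(enc$sdp_word_idx, rep(PAD_IDX, L - enc$m))
    didx <- c(enc$sdp_dep_idx, rep(PAD_IDX, L - enc$m))
    P <- cbind(tables$word[widx, , drop = FALSE],
               tables$deptype[didx, , drop = FALSE])
    return(list(X = X, P = P, sdp_widx = widx, sdp_didx = didx))
  }
  list(X = X, P = P)
}

#' Read and write word2vec text-format embeddings
#'
#' The text format: a header line `<vocab size> <dimension>` followed by one
#' line per word, `<word> <v1> ... <vd>`, space-separated.
#'
#' @param path file path.
#' @return numeric matrix with words as rownames.
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[1]), " ")[[1]])
  if (length(hdr) != 2L || anyNA(hdr))
    stopf("%s: malformed word2vec header '%s'", path, lines[1])
  body <- lines[-1]
  if (length(body) != hdr[1])
    stopf("%s: header declares %d rows, found %d", path, hdr[1], length(body))
  parts <- strsplit(body, " ", fixed = TRUE)
  words <- vapply(parts, `[[`, character(1), 1L)
  mat <- do.call(rbind, lapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[-1]))
    if (length(v) != hdr[2] || anyNA(v))
      stopf("%s: malformed embedding row for word '%s'", path, p[1])
    v
  }))
  rownames(mat) <- words
  mat
}

#' @rdname read_word2vec
#' @param mat numeric matrix with words as rownames.
#' @param digits significant digits written per component.
#' @export
write_word2vec <- function(mat, path, digits = 6L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
  fmt <- paste0("%.", digits, "g")
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(rownames(mat)[i],
                     paste(sprintf(fmt, mat[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
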