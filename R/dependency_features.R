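# Shortest dependency path extraction.
#
# The labeled, directed dependency parse is collapsed to an undirected graph
# (direction is dropped, the dependency type is kept on the edge) and the
# minimum-hop path between the two candidate entities' head tokens is found
# with Dijkstra's algorithm under unit edge weights. Ties between equal-length
# paths are broken by the lexicographically smallest token-index sequence, so
# the output is deterministic for any parse graph.

#' Build the undirected dependency graph of a sentence
#'
#' Each directed dependency edge becomes one undirected edge carrying its
#' dependency type; the edge count is preserved.
#'
#' @param sent a [sentence_graph()].
#' @return a `dep_graph`: list with `n` (token count), `adj` (per-token
#'   integer vector of neighbours) and `lab` (parallel character vector of
#'   dependency types).
#' @export
build_undirected_graph <- function(sent) {
  n <- nrow(sent$tokens)
  adj <- lapply(seq_len(n), function(i) integer())
  lab <- lapply(seq_len(n), function(i) character())
  if (nrow(sent$edges)) {
    for (i in seq_len(nrow(sent$edges))) {
      h <- sent$edges$head[i]; d <- sent$edges$dep[i]; t <- sent$edges$deprel[i]
      adj[[h]] <- c(adj[[h]], d); lab[[h]] <- c(lab[[h]], t)
      adj[[d]] <- c(adj[[d]], h); lab[[d]] <- c(lab[[d]], t)
    }
  }
  # sort neighbours for deterministic traversal order
  for (i in seq_len(n)) {
    o <- order(adj[[i]])
    adj[[i]] <- adj[[i]][o]
    lab[[i]] <- lab[[i]][o]
  }
  structure(list(n = n, adj = adj, lab = lab, n_edges = nrow(sent$edges)),
            class = "dep_graph")
}

lex_less <- function(a, b) {
  # TRUE when integer vector a precedes b lexicographically
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Shortest dependency path between two tokens
#'
#' Dijkstra under unit edge weights on the undirected dependency graph.
#' Among equal-length paths the lexicographically smallest token-index
#' sequence is returned, making the result deterministic.
#'
#' @param graph a `dep_graph` from [build_undirected_graph()].
#' @param e1_token,e2_token 1-based token indices of the two path endpoints
#'   (the entity head tokens).
#' @return a `shortest_path` (list with `token_idx`, `deptype_seq`, `m`
#'   where `m = length(token_idx)` and `length(deptype_seq) == m - 1`), or
#'   `NULL` when the tokens lie in disconnected components.
#' @export
shortest_dependency_path <- function(graph, e1_token, e2_token) {
  n <- graph$n
  if (e1_token < 1L || e1_token > n || e2_token < 1L || e2_token > n)
    stopf("token index out of range 1..%d", n)
  if (e1_token == e2_token)
    stopf("degenerate path: the two entities share head token %d", e1_token)
  dist <- rep(Inf, n)
  paths <- vector("list", n)
  visited <- rep(FALSE, n)
  dist[e1_token] <- 0
  paths[[e1_token]] <- e1_token
  repeat {
    u <- 0L; bd <- Inf
    for (v in seq_len(n)) {
      if (visited[v] || !is.finite(dist[v])) next
      if (dist[v] < bd || (dist[v] == bd && lex_less(paths[[v]], paths[[u]]))) {
        u <- v; bd <- dist[v]
      }
    }
    if (u == 0L) break
    visited[u] <- TRUE
    if (u == e2_token) break
    for (w in graph$adj[[u]]) {
      nd <- dist[u] + 1
      cand <- c(paths[[u]], w)
      if (nd < dist[w] || (nd == dist[w] && lex_less(cand, paths[[w]]))) {
        dist[w] <- nd
        paths[[w]] <- cand
      }
    }
  }
  if (!is.finite(dist[e2_token])) return(NULL)
  tok <- paths[[e2_token]]
  structure(
    list(token_idx = tok, deptype_seq = path_edge_labels(graph, tok),
         m = length(tok)),
    class = "shortest_path"
  )
}

path_edge_labels <- function(graph, tok) {
  if (length(tok) < 2L) return(character())
  vapply(seq_len(length(tok) - 1L), function(i) {
    u <- tok[i]; v <- tok[i + 1L]
    j <- match(v, graph$adj[[u]])
    graph$lab[[u]][j]
  }, character(1))
}

#' @export
print.shortest_path <- function(x, ...) {
  cat(sprintf("<shortest_path m=%d: %s | %s>\n", x$m,
              paste(x$token_idx, collapse = "-"),
              paste(x$deptype_seq, collapse = ",")))
  invisible(x)
}

#' Reverse a shortest path
#'
#' @param path a `shortest_path`.
#' @return the path with token and dependency-type sequences reversed.
#' @export
reverse_path <- function(path) {
  path$token_idx <- rev(path$token_idx)
  path$deptype_seq <- rev(path$deptype_seq)
  path
}

#' Orient a dependency path by entity-type priority
#'
#' Tasks with a `type_priority` (Bacteria-Biotope: Microorganism first)
#' always process the path from the priority-type entity towards the other
#' entity, regardless of sentence position. Without a priority match the
#' path is left in sentence order.
#'
#' @param path a `shortest_path` whose first token belongs to `e1`.
#' @param e1,e2 entity records (with `etype`), `e1` owning the path's first
#'   endpoint.
#' @param rules a [task_config()].
#' @return the oriented `shortest_path`; attribute `"reversed"` records
#'   whether the argument order was flipped.
#' @export
orient_path <- function(path, e1, e2, rules) {
  pri <- rules$type_priority
  p1 <- e1$etype %in% pri
  p2 <- e2$etype %in% pri
  rev_it <- p2 && !p1
  out <- if (rev_it) reverse_path(path) else path
  attr(out, "reversed") <- rev_it
  out
}

#' Token index used as an entity's path endpoint
#'
#' English noun phrases are usually head-final, so the entity's last token is
#' used as its dependency-path endpoint by default.
#'
#' @param entity an entity record with a resolved `token_span`.
#' @param head_rule `"last"` (default) or `"first"`.
#' @return a 1-based sentence-local token index.
#' @export
entity_head_token <- function(entity, head_rule = c("last", "first")) {
  head_rule <- match.arg(head_rule)
  if (is.null(entity$token_span))
    stopf("entity %s has no resolved token span", entity$id %||% "?")
  if (head_rule == "last") entity$token_span[2] else entity$token_span[1]
}

# Connected components by BFS; used to drop path-less candidate pairs.
graph_components <- function(graph) {
  comp <- rep(0L, graph$n)
  cur <- 0L
  for (s in seq_len(graph$n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in graph$adj[[u]]) {
        if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}
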