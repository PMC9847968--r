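#' Configuration for the per-vertex network metrics
#'
#' @param h Number of random-walk steps for the walk entropy (default 3;
#'   `h = 1` degenerates to the log of the vertex degree).
#' @param q PageRank amortization (damping) factor, conventionally 0.85.
#' @param pagerank_tol L1 convergence tolerance of the PageRank iteration.
#' @param pagerank_max_iter Iteration cap; exceeding it is an error.
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(h = 3, q = 0.85, pagerank_tol = 1e-10,
                          pagerank_max_iter = 1000) {
  stopifnot(h >= 1, q > 0, q < 1, pagerank_tol > 0, pagerank_max_iter >= 1)
  structure(list(h = as.integer(h), q = q, pagerank_tol = pagerank_tol,
                 pagerank_max_iter = as.integer(pagerank_max_iter)),
            class = "metric_config")
}

## Canonical channel order of the eight metrics in the rhythm image.
#' Metric names in canonical channel order
#'
#' The fixed order of the eight per-vertex metrics used for the rhythm
#' image channels: centrality (betweenness), clustering, eccentricity,
#' entropy, global efficiency, local efficiency, PageRank, vulnerability.
#' @return Character vector of length 8.
#' @export
rhythm_metrics <- function() {
  c("betweenness", "clustering", "eccentricity", "entropy",
    "global_efficiency", "local_efficiency", "pagerank", "vulnerability")
}

as_adjacency <- function(g) {
  A <- pass_adjacency(g)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (is.null(rownames(A))) {
    ids <- as.character(seq_len(nrow(A)) - 1L)
    dimnames(A) <- list(ids, ids)
  }
  A
}

## Hop-distance matrix (Inf for unreachable pairs). Breadth-first search
## by boolean closure: with M = A | I, the entries first becoming TRUE in
## M^k are exactly the pairs at distance k. Graphs here have <= 11
## vertices, so the k dense 0/1 products are cheap.
hop_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n, dimnames = dimnames(A))
  diag(d) <- 0
  if (n == 1L) return(d)
  M <- (A > 0) + diag(1, n)
  cur <- M > 0
  for (k in seq_len(n - 1L)) {
    new <- cur & !is.finite(d)
    if (!any(new)) break
    d[new] <- k
    cur <- (cur %*% M) > 0
  }
  d
}

#' Normalized betweenness centrality
#'
#' Sum over ordered vertex pairs (s, t), s != t, of the fraction of
#' shortest s-t paths passing through v (with the conventions that the
#' count is 1 when s = t and 0 when v is an endpoint), normalized by
#' (n - 1)(n - 2) so values lie in `[0, 1]`. Unreachable pairs contribute
#' nothing. Graphs with fewer than three vertices return all zeros (the
#' normalization is undefined there).
#'
#' @param g A `pass_graph` or adjacency matrix.
#' @return Named numeric vector, one value per vertex.
#' @export
betweenness_centrality <- function(g) {
  A <- as_adjacency(g)
  n <- nrow(A)
  out <- stats::setNames(numeric(n), rownames(A))
  if (n < 3L) return(out)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  b <- igraph::betweenness(ig, directed = FALSE, normalized = FALSE)
  # igraph sums over unordered pairs; the ordered-pair sum is twice that
  out[] <- 2 * as.numeric(b) / ((n - 1) * (n - 2))
  out
}

#' Vertex eccentricity
#'
#' Maximum hop distance from a vertex to any vertex it can reach. On
#' disconnected graphs the maximum is restricted to the vertex's connected
#' component; an isolated vertex has eccentricity 0.
#'
#' @inheritParams betweenness_centrality
#' @return Named numeric vector (hops).
#' @export
vertex_eccentricity <- function(g) {
  d <- hop_distances(as_adjacency(g))
  apply(d, 1L, function(row) {
    r <- row[is.finite(row)]
    if (length(r) <= 1L) 0 else max(r)
  })
}

#' Per-vertex global efficiency
#'
#' `E(v) = sum_{j != v} (1 / d(v, j)) / (n - 1)`, with `1/d = 0` for
#' unreachable pairs, where `n` is the number of vertices of the graph.
#'
#' @inheritParams betweenness_centrality
#' @return Named numeric vector in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  A <- as_adjacency(g)
  global_efficiency_from_dist(hop_distances(A))
}

global_efficiency_from_dist <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(stats::setNames(0, rownames(d)))
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' Per-vertex local efficiency
#'
#' For each vertex v, take the subgraph induced by the neighbours of v
#' (v itself excluded), compute the per-vertex global efficiency of each
#' neighbour within that subgraph, and average over the neighbours. A
#' degree-0 vertex scores 0, and a single-vertex neighbour subgraph
#' contributes 0.
#'
#' @inheritParams betweenness_centrality
#' @return Named numeric vector in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  A <- as_adjacency(g)
  n <- nrow(A)
  out <- stats::setNames(numeric(n), rownames(A))
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0L) next
    if (length(nb) == 1L) { out[v] <- 0; next }
    sub <- A[nb, nb, drop = FALSE]
    out[v] <- mean(global_efficiency_from_dist(hop_distances(sub)))
  }
  out
}

#' Per-vertex vulnerability
#'
#' `V(v) = 1 - Eloc(v) / E(v)`: the drop in efficiency when v is removed,
#' expressed through its local and global efficiencies. Defined as 0 when
#' the global efficiency is 0 (isolated vertex or edgeless graph).
#'
#' @inheritParams betweenness_centrality
#' @return Named numeric vector (may be negative when the neighbourhood is
#'   more efficient than the whole graph around v).
#' @export
vertex_vulnerability <- function(g) {
  A <- as_adjacency(g)
  E <- global_efficiency(A)
  Eloc <- local_efficiency(A)
  out <- ifelse(E > 0, 1 - Eloc / E, 0)
  stats::setNames(out, rownames(A))
}

#' Local clustering coefficient
#'
#' `C(v) = 2 T(v) / (deg(v) (deg(v) - 1))` where `T(v)` counts the
#' triangles through v; 0 for vertices of degree below 2.
#'
#' @inheritParams betweenness_centrality
#' @return Named numeric vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  A <- as_adjacency(g)
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  out <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  stats::setNames(out, rownames(A))
}

#' h-step random-walk entropy
#'
#' Shannon entropy (natural log) of the h-step transition distribution of
#' the simple random walk out of each vertex: row v of `P^h` where
#' `P = D^{-1} A`. Isolated vertices (no transition distribution) score 0,
#' as does any `0 * log 0` term.
#'
#' @inheritParams betweenness_centrality
#' @param config A [metric_config()]; `config$h` sets the walk length.
#' @return Named numeric vector in nats, `>= 0`.
#' @export
walk_entropy <- function(g, config = metric_config()) {
  A <- as_adjacency(g)
  deg <- rowSums(A)
  P <- A / ifelse(deg > 0, deg, 1)
  P[deg == 0, ] <- 0
  Ph <- P
  if (config$h > 1L) for (i in seq_len(config$h - 1L)) Ph <- Ph %*% P
  ent <- apply(Ph, 1L, function(p) {
    p <- p[p > 0]
    if (!length(p)) 0 else -sum(p * log(p))
  })
  stats::setNames(ent, rownames(A))
}

#' PageRank for undirected graphs
#'
#' Fixed point of `p(i) = (1 - q)/n + q * sum_{j in nei(i)} p(j)/deg(j)`,
#' solved by iteration from the uniform vector. Because that recurrence
#' does not conserve probability mass when isolated vertices are present,
#' the vector is renormalized to sum 1 after every sweep; convergence is
#' declared when the L1 change drops below `config$pagerank_tol`.
#'
#' @inheritParams walk_entropy
#' @return Named numeric vector summing to 1.
#' @export
pagerank_centrality <- function(g, config = metric_config()) {
  A <- as_adjacency(g)
  n <- nrow(A)
  if (n == 1L) return(stats::setNames(1, rownames(A)))
  deg <- rowSums(A)
  q <- config$q
  p <- rep(1 / n, n)
  for (it in seq_len(config$pagerank_max_iter)) {
    contrib <- ifelse(deg > 0, p / deg, 0)
    pn <- (1 - q) / n + q * as.numeric(A %*% contrib)
    pn <- pn / sum(pn)
    if (sum(abs(pn - p)) < config$pagerank_tol)
      return(stats::setNames(pn, rownames(A)))
    p <- pn
  }
  stop(sprintf(
    "PageRank failed to converge in %d iterations (residual %.3g)",
    config$pagerank_max_iter, sum(abs(pn - p))))
}

#' All eight per-vertex metrics of a pass graph
#'
#' @inheritParams walk_entropy
#' @return data.frame with one row per vertex: `player` plus the eight
#'   metric columns named as in [rhythm_metrics()]. Deterministic: no
#'   randomness is involved.
#' @export
compute_all_metrics <- function(g, config = metric_config()) {
  A <- as_adjacency(g)
  d <- hop_distances(A)
  E <- global_efficiency_from_dist(d)
  Eloc <- local_efficiency(A)
  data.frame(
    player = rownames(A),
    betweenness = as.numeric(betweenness_centrality(A)),
    clustering = as.numeric(clustering_coefficient(A)),
    eccentricity = apply(d, 1L, function(row) {
      r <- row[is.finite(row)]
      if (length(r) <= 1L) 0 else max(r)
    }),
    entropy = as.numeric(walk_entropy(A, config)),
    global_efficiency = as.numeric(E),
    local_efficiency = as.numeric(Eloc),
    pagerank = as.numeric(pagerank_centrality(A, config)),
    vulnerability = as.numeric(ifelse(E > 0, 1 - Eloc / E, 0)),
    row.names = NULL)
}
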