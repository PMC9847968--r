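# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: distances come from igraph, shortest paths from explicit
# enumeration, walks from recursive expansion, and the triangulation from
# the empty-circumcircle definition applied to all point triples.

random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  A + t(A)
}

oracle_distances <- function(A) {
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::distances(ig)
}

# Enumerate every shortest s-t path by DFS descending the distance-to-t
# field; count how many pass through each vertex.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  if (n < 3) return(out)
  d <- oracle_distances(A)
  for (s in 1:n) for (t in 1:n) {
    if (s == t || !is.finite(d[s, t])) next
    paths <- list()
    walk <- function(v, trail) {
      if (v == t) { paths[[length(paths) + 1L]] <<- trail; return() }
      for (u in which(A[v, ] > 0))
        if (d[u, t] == d[v, t] - 1) walk(u, c(trail, u))
    }
    walk(s, s)
    sigma <- length(paths)
    through <- numeric(n)
    for (pth in paths) {
      inner <- setdiff(pth, c(s, t))
      through[inner] <- through[inner] + 1
    }
    out <- out + through / sigma
  }
  out / ((n - 1) * (n - 2))
}

oracle_eccentricity <- function(A) {
  d <- oracle_distances(A)
  apply(d, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) <= 1) 0 else max(r)
  })
}

oracle_global_efficiency <- function(A) {
  d <- oracle_distances(A)
  n <- nrow(A)
  if (n == 1) return(0)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  sapply(1:n, function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) return(0)
    if (length(nb) == 1) return(0)
    mean(oracle_global_efficiency(A[nb, nb, drop = FALSE]))
  })
}

oracle_vulnerability <- function(A) {
  E <- oracle_global_efficiency(A)
  Eloc <- oracle_local_efficiency(A)
  ifelse(E > 0, 1 - Eloc / E, 0)
}

# Triangle counting by explicit triple enumeration.
oracle_clustering <- function(A) {
  n <- nrow(A)
  sapply(1:n, function(v) {
    deg <- sum(A[v, ])
    if (deg < 2) return(0)
    tri <- 0
    nb <- which(A[v, ] > 0)
    for (a in seq_along(nb)) for (b in seq_len(a - 1))
      if (A[nb[a], nb[b]] > 0) tri <- tri + 1
    2 * tri / (deg * (deg - 1))
  })
}

# h-step walk distribution by recursive expansion of every walk.
oracle_walk_entropy <- function(A, h) {
  n <- nrow(A)
  deg <- rowSums(A)
  sapply(1:n, function(v) {
    prob <- numeric(n)
    expand <- function(u, p, steps) {
      if (steps == 0) { prob[u] <<- prob[u] + p; return() }
      if (deg[u] == 0) return()
      for (w in which(A[u, ] > 0)) expand(w, p / deg[u], steps - 1)
    }
    expand(v, 1, h)
    pp <- prob[prob > 0]
    if (!length(pp)) 0 else -sum(pp * log(pp))
  })
}

# Independent power iteration, written vertex-by-vertex.
oracle_pagerank <- function(A, q = 0.85, tol = 1e-13, iters = 5000) {
  n <- nrow(A)
  deg <- rowSums(A)
  p <- rep(1 / n, n)
  for (i in seq_len(iters)) {
    pn <- numeric(n)
    for (v in 1:n) {
      acc <- 0
      for (u in which(A[v, ] > 0)) acc <- acc + p[u] / deg[u]
      pn[v] <- (1 - q) / n + q * acc
    }
    pn <- pn / sum(pn)
    if (sum(abs(pn - p)) < tol) return(pn)
    p <- pn
  }
  p
}

# Every pair lying on some circle empty of all other points is a Delaunay
# edge; for point sets in general position the empty-circumcircle
# triangles give exactly those pairs.
oracle_delaunay <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  edges <- matrix(integer(), 0, 2)
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    tri <- pts[c(a, b, cc), ]
    d <- 2 * (tri[1, 1] * (tri[2, 2] - tri[3, 2]) +
              tri[2, 1] * (tri[3, 2] - tri[1, 2]) +
              tri[3, 1] * (tri[1, 2] - tri[2, 2]))
    if (abs(d) < 1e-12) next
    a2 <- rowSums(tri^2)
    ux <- (a2[1] * (tri[2, 2] - tri[3, 2]) + a2[2] * (tri[3, 2] - tri[1, 2]) +
           a2[3] * (tri[1, 2] - tri[2, 2])) / d
    uy <- (a2[1] * (tri[3, 1] - tri[2, 1]) + a2[2] * (tri[1, 1] - tri[3, 1]) +
           a2[3] * (tri[2, 1] - tri[1, 1])) / d
    r2 <- (tri[1, 1] - ux)^2 + (tri[1, 2] - uy)^2
    rest <- setdiff(1:n, c(a, b, cc))
    dd <- (pts[rest, 1] - ux)^2 + (pts[rest, 2] - uy)^2
    if (all(dd > r2 * (1 + 1e-12)))
      edges <- rbind(edges, c(a, b), c(a, cc), c(b, cc))
  }
  e <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                    pmax(edges[, 1], edges[, 2])))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

edge_key <- function(e) paste(e[, 1], e[, 2], sep = "-")
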