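## Delaunay triangulation (Bowyer-Watson) with the degenerate-input
## fallbacks needed so a pass graph exists for every frame:
##   < 3 points        -> complete graph on them
##   collinear points  -> chain between coordinate-sorted neighbours
##   coincident points -> deterministic 1e-6 m jitter keyed by point index

#' Delaunay edges of a planar point set
#'
#' Returns the edge set of the Delaunay triangulation (empty-circumcircle
#' property) of the given points. Degenerate inputs never fail: fewer than
#' three points give the complete graph, collinear points give the chain
#' between coordinate-sorted neighbours, and coincident points receive a
#' deterministic micro-jitter (1e-6 m, keyed by point index) before
#' triangulating.
#'
#' @param points Numeric matrix with two columns (x, y), one row per point.
#' @return Integer matrix with two columns: 1-based row indices into
#'   `points`, each row one undirected edge with `[,1] < [,2]`. Zero rows
#'   for a single point.
#' @export
#' @examples
#' delaunay_edges(rbind(c(0, 0), c(4, 0), c(5, 3), c(1, 4)))
delaunay_edges <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must have two columns (x, y)")
  n <- nrow(points)
  no_edges <- matrix(integer(), ncol = 2L,
                     dimnames = list(NULL, c("i", "j")))
  if (n == 0L) stop("at least one point is required")
  if (n == 1L) return(no_edges)
  points <- jitter_coincident(points)
  if (n == 2L) return(matrix(c(1L, 2L), ncol = 2L,
                             dimnames = list(NULL, c("i", "j"))))
  if (is_collinear(points)) return(chain_edges(points))
  for (attempt in 0:3) {
    pts <- if (attempt == 0L) points else
      points + deterministic_jitter(n, scale = 1e-6 * 10^attempt)
    e <- tryCatch(bowyer_watson(pts), error = function(err) NULL)
    if (!is.null(e)) return(e)
  }
  stop("Delaunay triangulation failed on a degenerate point set")
}

## Jitter exactly-coincident points so the triangulation is well defined.
jitter_coincident <- function(points) {
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  if (min(d) > 1e-9) return(points)
  points + deterministic_jitter(nrow(points), scale = 1e-6)
}

## Reproducible per-index displacement on a spiral; no RNG involved.
deterministic_jitter <- function(n, scale = 1e-6) {
  i <- seq_len(n)
  ang <- 2 * pi * i * (sqrt(5) - 1) / 2
  scale * i * cbind(cos(ang), sin(ang))
}

is_collinear <- function(points, tol = 1e-9) {
  v <- sweep(points[-1L, , drop = FALSE], 2L, points[1L, ])
  ref <- v[which.max(rowSums(v^2)), ]
  if (sum(ref^2) < tol^2) return(TRUE)
  cross <- v[, 1L] * ref[2L] - v[, 2L] * ref[1L]
  all(abs(cross) < tol * sqrt(sum(ref^2)))
}

chain_edges <- function(points) {
  v <- sweep(points, 2L, points[1L, ])
  ref <- v[which.max(rowSums(v^2)), ]
  ord <- order(v %*% ref)
  e <- cbind(ord[-length(ord)], ord[-1L])
  e <- t(apply(e, 1L, sort))
  storage.mode(e) <- "integer"
  dimnames(e) <- list(NULL, c("i", "j"))
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

## Circumcircles of triangles (rows of `tri` index into P): centre (x, y)
## and squared radius per row, vectorized.
circumcircles <- function(P, tri) {
  ax <- P[tri[, 1L], 1L]; ay <- P[tri[, 1L], 2L]
  bx <- P[tri[, 2L], 1L]; by <- P[tri[, 2L], 2L]
  cx <- P[tri[, 3L], 1L]; cy <- P[tri[, 3L], 2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (any(abs(d) < 1e-12)) stop("degenerate triangle")
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  cbind(ux, uy, (ax - ux)^2 + (ay - uy)^2, deparse.level = 0)
}

## Containment test for triangles touching the bounding "super" vertices,
## taken in the symbolic limit where those vertices lie at infinity: such
## circumcircles degenerate to half-planes, so orientation tests replace
## the numeric incircle test (which would otherwise need the super
## triangle to dominate every real circumcircle, an unbounded quantity).
super_incircle <- function(t3, p, P, n) {
  sv <- t3[t3 > n]; rv <- t3[t3 <= n]
  if (length(sv) == 3L) return(TRUE)
  if (length(sv) == 1L) {
    a <- P[rv[1L], ]; b <- P[rv[2L], ]; s <- P[sv, ]
    o1 <- (b[1L] - a[1L]) * (p[2L] - a[2L]) -
          (b[2L] - a[2L]) * (p[1L] - a[1L])
    o2 <- (b[1L] - a[1L]) * (s[2L] - a[2L]) -
          (b[2L] - a[2L]) * (s[1L] - a[1L])
    return(o1 * o2 > 0)
  }
  a <- P[rv, ]; s1 <- P[sv[1L], ]; s2 <- P[sv[2L], ]
  nvec <- c(-(s2[2L] - s1[2L]), s2[1L] - s1[1L])
  sum((p - a) * nvec) * sum((s1 - a) * nvec) > 0
}

bowyer_watson <- function(pts) {
  n <- nrow(pts)
  cx <- mean(range(pts[, 1L])); cy <- mean(range(pts[, 2L]))
  span <- max(diff(range(pts[, 1L])), diff(range(pts[, 2L])), 1)
  big <- 64 * span
  P <- rbind(pts,
             c(cx - 2 * big, cy - big),
             c(cx + 2 * big, cy - big),
             c(cx, cy + 2 * big))
  tri <- matrix(n + c(1L, 2L, 3L), nrow = 1L)
  cc <- matrix(NA_real_, 1L, 3L)  # circumcircles of real triangles only
  nkey <- n + 4L
  for (i in seq_len(n)) {
    p <- P[i, ]
    is_real <- !is.na(cc[, 1L])
    inside <- logical(nrow(tri))
    if (any(is_real))
      inside[is_real] <-
        (p[1L] - cc[is_real, 1L])^2 + (p[2L] - cc[is_real, 2L])^2 <=
        cc[is_real, 3L] * (1 + 1e-12)
    for (j in which(!is_real))
      inside[j] <- super_incircle(tri[j, ], p, P, n)
    bad <- which(inside)
    if (!length(bad)) stop("point outside all circumcircles")
    be <- rbind(tri[bad, c(1L, 2L), drop = FALSE],
                tri[bad, c(2L, 3L), drop = FALSE],
                tri[bad, c(3L, 1L), drop = FALSE])
    be <- cbind(pmin(be[, 1L], be[, 2L]), pmax(be[, 1L], be[, 2L]))
    key <- be[, 1L] * nkey + be[, 2L]
    once <- !(key %in% key[duplicated(key)])
    boundary <- be[once, , drop = FALSE]
    tri <- tri[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(boundary, i)
    newcc <- matrix(NA_real_, nrow(newt), 3L)
    real_new <- rowSums(newt > n) == 0L
    if (any(real_new))
      newcc[real_new, ] <- circumcircles(P, newt[real_new, , drop = FALSE])
    tri <- rbind(tri, newt)
    cc <- rbind(cc, newcc)
  }
  keep <- rowSums(tri > n) == 0L
  tri <- tri[keep, , drop = FALSE]
  if (nrow(tri) == 0L) stop("no triangles survived")
  e <- rbind(tri[, c(1L, 2L), drop = FALSE],
             tri[, c(2L, 3L), drop = FALSE],
             tri[, c(3L, 1L), drop = FALSE])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  storage.mode(e) <- "integer"
  dimnames(e) <- list(NULL, c("i", "j"))
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}
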