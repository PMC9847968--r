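## Batched variants of the network primitives. Activations are arrays
## [H, W, C, B] (B = batch); dense activations are matrices [features, B].
## Batching moves the per-sample R interpreter overhead into single large
## matrix operations, which is what makes training practical in pure R.

im2col_cache_b <- new.env(parent = emptyenv())

## Precomputed flat index maps for one (H, W, C, B) configuration:
##   $gather  — length H*W*B*9*C, ordered so that
##              matrix(xp[gather], H*W*B, 9*C) is the im2col matrix with
##              rows (pos, b) and columns (k, c), k fastest;
##   $scatter — list of 9 index vectors, scatter[[k]][(pos, b, c)] is the
##              padded-array cell receiving column group k of d(cols);
##   $colsel  — list of 9 column-index vectors selecting group k from the
##              (H*W*B) x (9*C) gradient matrix in (pos, b, c) order.
im2col_maps <- function(H, W, C, B) {
  key <- paste(H, W, C, B, sep = "x")
  if (!is.null(im2col_cache_b[[key]])) return(im2col_cache_b[[key]])
  base <- im2col_idx(H, W)                      # (H*W) x 9
  plane <- (H + 2L) * (W + 2L)
  HW <- H * W
  ## gather order: pos, b, k, c
  off_b <- (seq_len(B) - 1L) * plane * C
  off_c <- (seq_len(C) - 1L) * plane
  gather <- integer(HW * B * 9L * C)
  pos <- 1L
  block <- HW * B
  for (cc in seq_len(C)) for (k in 1:9) {
    gather[pos:(pos + block - 1L)] <-
      rep(base[, k] + off_c[cc], times = B) + rep(off_b, each = HW)
    pos <- pos + block
  }
  scatter <- vector("list", 9L)
  colsel <- vector("list", 9L)
  for (k in 1:9) {
    ## order: pos, b, c
    scatter[[k]] <- as.integer(
      rep(base[, k], times = B * C) +
        rep(rep(off_b, each = HW), times = C) +
        rep(off_c, each = HW * B))
    colsel[[k]] <- seq(k, 9L * C, by = 9L)
  }
  maps <- list(gather = gather, scatter = scatter, colsel = colsel)
  im2col_cache_b[[key]] <- maps
  maps
}

stack_images <- function(xlist) {
  d <- dim(xlist[[1L]])
  array(unlist(xlist, use.names = FALSE), c(d, length(xlist)))
}

conv3x3_fwd_b <- function(x, Wt, b) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]; B <- d[4L]
  xp <- array(0, c(H + 2L, W + 2L, C, B))
  xp[2:(H + 1L), 2:(W + 1L), , ] <- x
  maps <- im2col_maps(H, W, C, B)
  M <- matrix(xp[maps$gather], H * W * B, 9L * C)
  out <- M %*% Wt
  out <- out + rep(b, each = H * W * B)
  list(out = array(aperm(array(out, c(H * W, B, ncol(Wt))), c(1L, 3L, 2L)),
                   c(H, W, ncol(Wt), B)),
       cols = M)
}

conv3x3_bwd_b <- function(dout, cols, Wt, H, W, C, B) {
  Cout <- dim(dout)[3L]
  dmat <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), H * W * B, Cout)
  dW <- crossprod(cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(Wt)
  maps <- im2col_maps(H, W, C, B)
  dxp <- numeric((H + 2L) * (W + 2L) * C * B)
  for (k in 1:9) {
    ii <- maps$scatter[[k]]
    dxp[ii] <- dxp[ii] + as.vector(dcols[, maps$colsel[[k]]])
  }
  dxp <- array(dxp, c(H + 2L, W + 2L, C, B))
  list(dx = dxp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE], dW = dW, db = db)
}

maxpool_fwd_b <- function(x) {
  d <- dim(x); H <- d[1L]; W <- d[2L]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  a <- x[io, jo, , , drop = FALSE]
  b <- x[io + 1L, jo, , , drop = FALSE]
  cc <- x[io, jo + 1L, , , drop = FALSE]
  dd <- x[io + 1L, jo + 1L, , , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  sel <- array(4L, dim(out))
  sel[cc == out] <- 3L
  sel[b == out] <- 2L
  sel[a == out] <- 1L
  list(out = out, sel = sel)
}

maxpool_bwd_b <- function(dout, sel, H, W) {
  d <- dim(dout)
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  dx <- array(0, c(H, W, d[3L], d[4L]))
  route <- function(mask) { g <- array(0, d); g[mask] <- dout[mask]; g }
  dx[io, jo, , ] <- route(sel == 1L)
  dx[io + 1L, jo, , ] <- route(sel == 2L)
  dx[io, jo + 1L, , ] <- route(sel == 3L)
  dx[io + 1L, jo + 1L, , ] <- route(sel == 4L)
  dx
}

resize_fwd_b <- function(x, Ry, Rx) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]; B <- d[4L]
  Ho <- nrow(Ry); Wo <- nrow(Rx)
  y <- array(Ry %*% matrix(x, H, W * C * B), c(Ho, W, C, B))
  y <- aperm(y, c(2L, 1L, 3L, 4L))
  y <- array(Rx %*% matrix(y, W, Ho * C * B), c(Wo, Ho, C, B))
  aperm(y, c(2L, 1L, 3L, 4L))
}

resize_bwd_b <- function(dout, Ry, Rx) {
  d <- dim(dout); Ho <- d[1L]; Wo <- d[2L]; C <- d[3L]; B <- d[4L]
  H <- ncol(Ry); W <- ncol(Rx)
  y <- array(crossprod(Ry, matrix(dout, Ho, Wo * C * B)), c(H, Wo, C, B))
  y <- aperm(y, c(2L, 1L, 3L, 4L))
  y <- array(crossprod(Rx, matrix(y, Wo, H * C * B)), c(W, H, C, B))
  aperm(y, c(2L, 1L, 3L, 4L))
}

gap_fwd_b <- function(x) {
  d <- dim(x)
  matrix(.colMeans(matrix(x, d[1L] * d[2L], d[3L] * d[4L]),
                   d[1L] * d[2L], d[3L] * d[4L]),
         d[3L], d[4L])
}

gap_bwd_b <- function(dmat, H, W) {
  array(rep(as.vector(dmat), each = H * W) / (H * W),
        c(H, W, nrow(dmat), ncol(dmat)))
}

dense_fwd_b <- function(X, W, b) W %*% X + b
dense_bwd_b <- function(dout, X, W) {
  list(dX = crossprod(W, dout), dW = tcrossprod(dout, X),
       db = rowSums(dout))
}

softmax_b <- function(Z) {
  Z <- sweep(Z, 2L, apply(Z, 2L, max))
  E <- exp(Z)
  sweep(E, 2L, colSums(E), "/")
}
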