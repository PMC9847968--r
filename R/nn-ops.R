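## Minimal neural-network primitives (3x3 same-padding convolution via
## im2col, 2x2 max pooling, bilinear resize as a pair of interpolation
## matrices, dense layers, softmax cross-entropy, Adam). Feature maps are
## arrays [H, W, C]; weights live in flat named lists so the optimizer can
## treat them uniformly. Everything is deterministic given the RNG state.

im2col_cache <- new.env(parent = emptyenv())

## (H*W) x 9 linear indices into a zero-padded (H+2) x (W+2) matrix.
im2col_idx <- function(H, W) {
  key <- paste(H, W)
  if (!is.null(im2col_cache[[key]])) return(im2col_cache[[key]])
  Hp <- H + 2L
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L)
  k <- 1L
  for (dj in 0:2) for (di in 0:2) {
    idx[, k] <- (i + di) + (j + dj - 1L) * Hp
    k <- k + 1L
  }
  im2col_cache[[key]] <- idx
  idx
}

## x [H,W,Cin] -> list(out [H,W,Cout], cols) with weights Wt [9*Cin, Cout].
conv3x3_forward <- function(x, Wt, b) {
  H <- dim(x)[1L]; W <- dim(x)[2L]; Cin <- dim(x)[3L]
  idx <- im2col_idx(H, W)
  cols <- matrix(0, H * W, 9L * Cin)
  pad <- matrix(0, H + 2L, W + 2L)
  for (c in seq_len(Cin)) {
    pad[2:(H + 1L), 2:(W + 1L)] <- x[, , c]
    cols[, ((c - 1L) * 9L + 1L):(c * 9L)] <- pad[idx]
  }
  out <- sweep(cols %*% Wt, 2L, b, "+")
  list(out = array(out, c(H, W, length(b))), cols = cols)
}

conv3x3_backward <- function(dout, cols, Wt, H, W, Cin) {
  Cout <- dim(dout)[3L]
  dmat <- matrix(dout, H * W, Cout)
  dW <- crossprod(cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(Wt)
  idx <- im2col_idx(H, W)
  dx <- array(0, c(H, W, Cin))
  for (c in seq_len(Cin)) {
    dpad <- numeric((H + 2L) * (W + 2L))
    block <- dcols[, ((c - 1L) * 9L + 1L):(c * 9L), drop = FALSE]
    for (k in 1:9) dpad[idx[, k]] <- dpad[idx[, k]] + block[, k]
    dpadm <- matrix(dpad, H + 2L, W + 2L)
    dx[, , c] <- dpadm[2:(H + 1L), 2:(W + 1L)]
  }
  list(dx = dx, dW = dW, db = db)
}

relu <- function(x) pmax(x, 0)
relu_backward <- function(dout, x) dout * (x > 0)

## 2x2 max pool, stride 2; H and W must be even. Ties resolve to the
## first quadrant in scan order (deterministic).
maxpool_forward <- function(x) {
  H <- dim(x)[1L]; W <- dim(x)[2L]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  a <- x[io, jo, , drop = FALSE]
  b <- x[io + 1L, jo, , drop = FALSE]
  cc <- x[io, jo + 1L, , drop = FALSE]
  d <- x[io + 1L, jo + 1L, , drop = FALSE]
  out <- pmax(a, b, cc, d)
  sel <- array(4L, dim(out))
  sel[cc == out] <- 3L
  sel[b == out] <- 2L
  sel[a == out] <- 1L
  list(out = out, sel = sel)
}

maxpool_backward <- function(dout, sel, H, W) {
  C <- dim(dout)[3L]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  dx <- array(0, c(H, W, C))
  route <- function(mask) { g <- array(0, dim(dout)); g[mask] <- dout[mask]; g }
  dx[io, jo, ] <- route(sel == 1L)
  dx[io + 1L, jo, ] <- route(sel == 2L)
  dx[io, jo + 1L, ] <- route(sel == 3L)
  dx[io + 1L, jo + 1L, ] <- route(sel == 4L)
  dx
}

## Bilinear interpolation matrix mapping n_in samples to n_out samples
## (half-pixel-centre convention, edge clamped).
resize_matrix <- function(n_in, n_out) {
  R <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    s <- (o - 0.5) * n_in / n_out + 0.5
    s <- min(max(s, 1), n_in)
    lo <- floor(s); hi <- ceiling(s)
    w <- s - lo
    R[o, lo] <- R[o, lo] + (1 - w)
    if (hi != lo) R[o, hi] <- R[o, hi] + w else R[o, lo] <- 1
  }
  R
}

resize_forward <- function(x, Ry, Rx) {
  C <- dim(x)[3L]
  out <- array(0, c(nrow(Ry), nrow(Rx), C))
  for (c in seq_len(C)) out[, , c] <- Ry %*% x[, , c] %*% t(Rx)
  out
}

resize_backward <- function(dout, Ry, Rx) {
  C <- dim(dout)[3L]
  dx <- array(0, c(ncol(Ry), ncol(Rx), C))
  for (c in seq_len(C)) dx[, , c] <- crossprod(Ry, dout[, , c]) %*% Rx
  dx
}

gap_forward <- function(x) apply(x, 3L, mean)
gap_backward <- function(dvec, H, W) {
  array(rep(dvec, each = H * W) / (H * W), c(H, W, length(dvec)))
}

dense_forward <- function(x, W, b) as.numeric(W %*% x + b)
## returns dx, dW, db for one sample
dense_backward <- function(dout, x, W) {
  list(dx = as.numeric(crossprod(W, dout)),
       dW = outer(dout, x), db = dout)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

## He-normal initialisation for a fan_in -> fan_out weight matrix/array.
he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

## Adam step over flat lists of arrays (params, grads, state in place).
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Accumulate gradient lists elementwise.
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

grad_scale <- function(g, s) lapply(g, function(x) x * s)
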