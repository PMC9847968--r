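#' Classifier configuration
#'
#' Architecture: two 3x3 adapter convolutions map the 16 rhythm channels
#' to 3 (the first with ReLU), the result is bilinearly resized to
#' `input_resize` (at least 32 x 32, as the backbone expects), a pluggable
#' convolutional backbone produces a feature vector, and a dense head of 4
#' fully connected ReLU layers plus a 2-way softmax decision layer
#' classifies success vs failure.
#'
#' Backbones:
#' \describe{
#'   \item{`efficientnet_b0_topology`}{The default: stem + depthwise-
#'     separable stages with the EfficientNet-B0 stage widths
#'     (32, 16, 24, 40, 80, 112, 192, 320) and a 1280-channel 1x1 head,
#'     swish activations, global average pooling; feature vector length
#'     1280. Weights are seeded-random and frozen (no pretrained weights
#'     ship with the package), so with this backbone [fit_model()] trains
#'     the dense head only, transfer-learning style.}
#'   \item{`tiny_cnn`}{Three 3x3 conv + ReLU + 2x2 max-pool blocks
#'     (3 -> 8 -> 16 -> `feature_dim` channels) trained end to end together
#'     with the adapter and head. The desk-scale backbone used throughout
#'     the test-suite.}
#' }
#'
#' The loss is class-weighted cross-entropy optimized with Adam; balanced
#' accuracy on the validation set drives model selection and early
#' stopping (balanced accuracy itself is not differentiable).
#'
#' @param backbone `"efficientnet_b0_topology"` or `"tiny_cnn"`.
#' @param adapter_channels Channel counts of the two adapter convolutions
#'   (16 -> first -> second; the second must be 3).
#' @param input_resize Spatial size (rows, cols) after the adapter; both
#'   at least 32 and divisible by 8.
#' @param feature_dim Feature-vector length of the `tiny_cnn` backbone.
#' @param head_width Width of the 4 fully connected head layers.
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation
#'   balanced-accuracy improvement).
#' @param class_weighting Weight the cross-entropy inversely to class
#'   frequency (default on).
#' @param seed Integer seed; training is deterministic given it.
#' @return An object of class `model_config`.
#' @export
model_config <- function(backbone = c("efficientnet_b0_topology", "tiny_cnn"),
                         adapter_channels = c(8, 3),
                         input_resize = c(32, 32),
                         feature_dim = 32, head_width = 32,
                         lr = 1e-3, epochs = 100, batch_size = 8,
                         patience = 25, class_weighting = TRUE, seed = 1) {
  backbone <- match.arg(backbone)
  stopifnot(length(adapter_channels) == 2L, adapter_channels[2L] == 3L,
            length(input_resize) == 2L, all(input_resize >= 32),
            all(input_resize %% 8 == 0),
            feature_dim >= 2, head_width >= 2, lr > 0, epochs >= 1,
            batch_size >= 1, patience >= 1)
  structure(list(backbone = backbone, adapter_channels = adapter_channels,
                 input_resize = as.integer(input_resize),
                 feature_dim = as.integer(feature_dim),
                 head_width = as.integer(head_width),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 class_weighting = isTRUE(class_weighting),
                 seed = as.integer(seed)),
            class = "model_config")
}

MODEL_CLASSES <- c("failure", "success")

effnet_stages <- function() {
  ## (output width, stride) per stage, mirroring the B0 stage widths.
  list(c(16L, 1L), c(24L, 2L), c(40L, 2L), c(80L, 2L),
       c(112L, 1L), c(192L, 2L), c(320L, 1L))
}

#' Feature-vector length of a configured backbone
#' @param config A [model_config()].
#' @return 1280 for `efficientnet_b0_topology`, `feature_dim` for
#'   `tiny_cnn`.
#' @export
backbone_feature_length <- function(config) {
  if (config$backbone == "efficientnet_b0_topology") 1280L
  else config$feature_dim
}

init_params <- function(config) {
  ca <- config$adapter_channels
  p <- list(
    a1W = he_init(c(9L * 16L, ca[1L]), 9 * 16), a1b = numeric(ca[1L]),
    a2W = he_init(c(9L * ca[1L], 3L), 9 * ca[1L]), a2b = numeric(3L))
  if (config$backbone == "tiny_cnn") {
    Fd <- config$feature_dim
    p <- c(p, list(
      c1W = he_init(c(9L * 3L, 8L), 27), c1b = numeric(8L),
      c2W = he_init(c(9L * 8L, 16L), 72), c2b = numeric(16L),
      c3W = he_init(c(9L * 16L, Fd), 144), c3b = numeric(Fd)))
  } else {
    widths <- c(32L, vapply(effnet_stages(), `[`, integer(1L), 1L))
    p$e_stemW <- he_init(c(9L * 3L, 32L), 27); p$e_stemb <- numeric(32L)
    cin <- 32L
    for (s in seq_along(effnet_stages())) {
      w <- effnet_stages()[[s]][1L]
      p[[sprintf("e_dw%d", s)]] <- he_init(c(9L, cin), 9)
      p[[sprintf("e_dwb%d", s)]] <- numeric(cin)
      p[[sprintf("e_pw%d", s)]] <- he_init(c(cin, w), cin)
      p[[sprintf("e_pwb%d", s)]] <- numeric(w)
      cin <- w
    }
    p$e_headW <- he_init(c(cin, 1280L), cin); p$e_headb <- numeric(1280L)
  }
  Fd <- backbone_feature_length(config)
  w <- config$head_width
  dims <- c(Fd, w, w, w, w)
  for (l in 1:4) {
    p[[sprintf("h%dW", l)]] <- he_init(c(dims[l + 1L], dims[l]), dims[l])
    p[[sprintf("h%db", l)]] <- numeric(dims[l + 1L])
  }
  p$dW <- he_init(c(2L, w), w)
  p$db <- numeric(2L)
  p
}

#' Create an untrained possession-outcome model
#'
#' Weights are initialized (He-normal) from `config$seed`, so two models
#' built from the same configuration are identical.
#'
#' @param config A [model_config()].
#' @return Object of class `possession_model`.
#' @export
possession_model <- function(config = model_config()) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  structure(list(config = config, params = init_params(config),
                 classes = MODEL_CLASSES, trained = FALSE,
                 history = NULL),
            class = "possession_model")
}

#' @export
print.possession_model <- function(x, ...) {
  cat(sprintf("<possession_model> backbone %s (%d-d features), %s\n",
              x$config$backbone, backbone_feature_length(x$config),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

swish <- function(x) x / (1 + exp(-x))

stride2 <- function(x) {
  x[seq(1L, dim(x)[1L], 2L), seq(1L, dim(x)[2L], 2L), , drop = FALSE]
}

depthwise_forward <- function(x, Wt, b) {
  C <- dim(x)[3L]
  out <- array(0, dim(x))
  for (c in seq_len(C)) {
    o <- conv3x3_forward(x[, , c, drop = FALSE],
                         matrix(Wt[, c], ncol = 1L), b[c])
    out[, , c] <- o$out[, , 1L]
  }
  out
}

pointwise_forward <- function(x, Wt, b) {
  H <- dim(x)[1L]; W <- dim(x)[2L]
  m <- matrix(x, H * W, dim(x)[3L]) %*% Wt
  array(sweep(m, 2L, b, "+"), c(H, W, ncol(Wt)))
}

effnet_features <- function(p, r) {
  x <- swish(stride2(conv3x3_forward(r, p$e_stemW, p$e_stemb)$out))
  for (s in seq_along(effnet_stages())) {
    st <- effnet_stages()[[s]]
    x <- swish(depthwise_forward(x, p[[sprintf("e_dw%d", s)]],
                                 p[[sprintf("e_dwb%d", s)]]))
    if (st[2L] == 2L) x <- stride2(x)
    x <- swish(pointwise_forward(x, p[[sprintf("e_pw%d", s)]],
                                 p[[sprintf("e_pwb%d", s)]]))
  }
  x <- swish(pointwise_forward(x, p$e_headW, p$e_headb))
  gap_forward(x)
}

adapter_resize <- function(p, x, Ry, Rx, keep_cache = FALSE) {
  a1c <- conv3x3_forward(x, p$a1W, p$a1b)
  a1 <- relu(a1c$out)
  a2c <- conv3x3_forward(a1, p$a2W, p$a2b)
  r <- resize_forward(a2c$out, Ry, Rx)
  if (!keep_cache) return(list(r = r))
  list(r = r, a1c = a1c, a1 = a1, a2c = a2c)
}

model_resizers <- function(config, input_dim) {
  list(Ry = resize_matrix(input_dim[1L], config$input_resize[1L]),
       Rx = resize_matrix(input_dim[2L], config$input_resize[2L]))
}

## Batched forward pass over xb [H, W, 16, B]; keep_cache retains the
## intermediates backprop needs. The (frozen) efficientnet topology runs
## per sample; the trainable tiny_cnn path is fully batched.
model_forward_b <- function(model, xb, keep_cache = FALSE) {
  p <- model$params
  cfg <- model$config
  B <- dim(xb)[4L]
  rs <- model_resizers(cfg, dim(xb))
  if (cfg$backbone == "tiny_cnn") {
    a1c <- conv3x3_fwd_b(xb, p$a1W, p$a1b); a1 <- relu(a1c$out)
    a2c <- conv3x3_fwd_b(a1, p$a2W, p$a2b)
    r <- resize_fwd_b(a2c$out, rs$Ry, rs$Rx)
    b1c <- conv3x3_fwd_b(r, p$c1W, p$c1b); b1 <- relu(b1c$out)
    p1 <- maxpool_fwd_b(b1)
    b2c <- conv3x3_fwd_b(p1$out, p$c2W, p$c2b); b2 <- relu(b2c$out)
    p2 <- maxpool_fwd_b(b2)
    b3c <- conv3x3_fwd_b(p2$out, p$c3W, p$c3b); b3 <- relu(b3c$out)
    p3 <- maxpool_fwd_b(b3)
    feat <- gap_fwd_b(p3$out)
  } else {
    feat <- vapply(seq_len(B), function(i) {
      ad <- adapter_resize(p, array(xb[, , , i], dim(xb)[1:3]),
                           rs$Ry, rs$Rx)
      effnet_features(p, ad$r)
    }, numeric(backbone_feature_length(cfg)))
    feat <- matrix(feat, backbone_feature_length(cfg), B)
  }
  h <- feat
  zs <- vector("list", 4L); hs <- vector("list", 5L)
  hs[[1L]] <- feat
  for (l in 1:4) {
    zs[[l]] <- dense_fwd_b(h, p[[sprintf("h%dW", l)]],
                           p[[sprintf("h%db", l)]])
    h <- relu(zs[[l]])
    hs[[l + 1L]] <- h
  }
  probs <- softmax_b(dense_fwd_b(h, p$dW, p$db))
  out <- list(probs = probs, feat = feat)
  if (keep_cache) {
    out$cache <- list(xb = xb, zs = zs, hs = hs, rs = rs)
    if (cfg$backbone == "tiny_cnn")
      out$cache <- c(out$cache,
                     list(a1c = a1c, a1 = a1, a2c = a2c,
                          b1c = b1c, b1 = b1, p1 = p1, b2c = b2c, b2 = b2,
                          p2 = p2, b3c = b3c, b3 = b3, p3 = p3))
  }
  out
}

model_forward <- function(model, x, keep_cache = FALSE) {
  fwd <- model_forward_b(model, array(x, c(dim(x), 1L)), keep_cache)
  list(probs = as.numeric(fwd$probs), feat = as.numeric(fwd$feat),
       cache = fwd$cache)
}

## Gradients of the summed weighted CE loss over the batch.
## dlogits[, i] = w_i * (p_i - onehot(y_i)).
model_backward_b <- function(model, fwd, y_idx, weights) {
  p <- model$params
  cfg <- model$config
  ca <- fwd$cache
  B <- length(y_idx)
  g <- list()
  dlog <- fwd$probs
  dlog[cbind(y_idx, seq_len(B))] <- dlog[cbind(y_idx, seq_len(B))] - 1
  dlog <- sweep(dlog, 2L, weights, "*")
  d <- dense_bwd_b(dlog, ca$hs[[5L]], p$dW)
  g$dW <- d$dW; g$db <- d$db
  dh <- d$dX
  for (l in 4:1) {
    dz <- relu_backward(dh, ca$zs[[l]])
    d <- dense_bwd_b(dz, ca$hs[[l]], p[[sprintf("h%dW", l)]])
    g[[sprintf("h%dW", l)]] <- d$dW
    g[[sprintf("h%db", l)]] <- d$db
    dh <- d$dX
  }
  if (cfg$backbone != "tiny_cnn") return(g)  # frozen backbone + adapter
  H <- dim(ca$b1)[1L]; W <- dim(ca$b1)[2L]
  dp3 <- gap_bwd_b(dh, dim(ca$p3$out)[1L], dim(ca$p3$out)[2L])
  db3 <- maxpool_bwd_b(dp3, ca$p3$sel, dim(ca$b3)[1L], dim(ca$b3)[2L])
  dz3 <- relu_backward(db3, ca$b3c$out)
  cb <- conv3x3_bwd_b(dz3, ca$b3c$cols, p$c3W,
                      dim(ca$b3)[1L], dim(ca$b3)[2L],
                      dim(ca$p2$out)[3L], B)
  g$c3W <- cb$dW; g$c3b <- cb$db
  db2 <- maxpool_bwd_b(cb$dx, ca$p2$sel, dim(ca$b2)[1L], dim(ca$b2)[2L])
  dz2 <- relu_backward(db2, ca$b2c$out)
  cb <- conv3x3_bwd_b(dz2, ca$b2c$cols, p$c2W,
                      dim(ca$b2)[1L], dim(ca$b2)[2L],
                      dim(ca$p1$out)[3L], B)
  g$c2W <- cb$dW; g$c2b <- cb$db
  db1 <- maxpool_bwd_b(cb$dx, ca$p1$sel, H, W)
  dz1 <- relu_backward(db1, ca$b1c$out)
  cb <- conv3x3_bwd_b(dz1, ca$b1c$cols, p$c1W, H, W, 3L, B)
  g$c1W <- cb$dW; g$c1b <- cb$db
  da2 <- resize_bwd_b(cb$dx, ca$rs$Ry, ca$rs$Rx)
  Hx <- dim(ca$xb)[1L]; Wx <- dim(ca$xb)[2L]
  cb <- conv3x3_bwd_b(da2, ca$a2c$cols, p$a2W, Hx, Wx,
                      cfg$adapter_channels[1L], B)
  g$a2W <- cb$dW; g$a2b <- cb$db
  da1 <- relu_backward(cb$dx, ca$a1c$out)
  cb <- conv3x3_bwd_b(da1, ca$a1c$cols, p$a1W, Hx, Wx, 16L, B)
  g$a1W <- cb$dW; g$a1b <- cb$db
  g
}

## Class probabilities for a list of images, in inference chunks.
model_predict_probs <- function(model, xlist, chunk = 64L) {
  out <- matrix(0, 2L, length(xlist))
  for (start in seq(1L, length(xlist), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(xlist))
    out[, idx] <- model_forward_b(model, stack_images(xlist[idx]))$probs
  }
  out
}

to_y_idx <- function(y) {
  if (is.logical(y)) return(ifelse(y, 2L, 1L))
  if (is.factor(y) || is.character(y)) {
    i <- match(as.character(y), MODEL_CLASSES)
    if (anyNA(i)) stop("labels must be 'failure'/'success' or logical")
    return(i)
  }
  stop("labels must be logical or 'failure'/'success'")
}

#' Train the possession-outcome classifier
#'
#' Optimizes class-weighted cross-entropy with Adam; after every epoch the
#' balanced accuracy on the validation set is computed and the weights with
#' the best validation balanced accuracy are kept (early stopping after
#' `patience` epochs without improvement). Deterministic given
#' `config$seed`. With the `efficientnet_b0_topology` backbone only the
#' dense head is trained (the seeded adapter/backbone stay frozen); with
#' `tiny_cnn` the adapter, backbone and head all train.
#'
#' @param x_train,x_val Lists of `11 x T x 16` image tensors (normalized;
#'   see [assemble_image()]).
#' @param y_train,y_val Labels: logical (`TRUE` = success) or
#'   `"failure"`/`"success"`.
#' @param config A [model_config()].
#' @return A trained `possession_model` with a `history` data.frame
#'   (epoch, train loss, validation balanced accuracy).
#' @export
fit_model <- function(x_train, y_train, x_val, y_val,
                      config = model_config()) {
  yt <- to_y_idx(y_train)
  yv <- to_y_idx(y_val)
  if (length(unique(yt)) < 2L)
    stop("training set contains a single class; both are required")
  stopifnot(length(x_train) == length(yt), length(x_val) == length(yv))
  model <- possession_model(config)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed + 1L)

  n <- length(x_train)
  cw <- if (config$class_weighting) {
    tab <- tabulate(yt, 2L)
    n / (2 * tab)
  } else c(1, 1)
  trainable <- trainable_names(config)
  opt <- adam_init(model$params[trainable])
  best_ba <- -Inf; best_params <- model$params; wait <- 0L
  hist <- data.frame(epoch = integer(), loss = numeric(), val_ba = numeric())

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    total_loss <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      fwd <- model_forward_b(model, stack_images(x_train[idx]),
                             keep_cache = TRUE)
      w <- cw[yt[idx]]
      picked <- fwd$probs[cbind(yt[idx], seq_along(idx))]
      total_loss <- total_loss - sum(w * log(pmax(picked, 1e-12)))
      acc <- model_backward_b(model, fwd, yt[idx], w)
      acc <- grad_scale(acc[trainable], 1 / length(idx))
      upd <- adam_step(model$params[trainable], acc, opt, config$lr)
      model$params[trainable] <- upd$params
      opt <- upd$state
    }
    val_ba <- balanced_accuracy(
      apply(model_predict_probs(model, x_val), 2L, which.max), yv)
    hist <- rbind(hist, data.frame(epoch = epoch, loss = total_loss / n,
                                   val_ba = val_ba))
    if (val_ba > best_ba + 1e-12) {
      best_ba <- val_ba; best_params <- model$params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model$params <- best_params
  model$trained <- TRUE
  model$history <- hist
  model$val_balanced_accuracy <- best_ba
  model
}

trainable_names <- function(config) {
  head_nms <- c(sprintf("h%dW", 1:4), sprintf("h%db", 1:4), "dW", "db")
  if (config$backbone == "tiny_cnn")
    c("a1W", "a1b", "a2W", "a2b", "c1W", "c1b", "c2W", "c2b",
      "c3W", "c3b", head_nms)
  else head_nms
}

#' Class probabilities for one rhythm image
#'
#' @param model A `possession_model`.
#' @param image An `11 x T x 16` tensor.
#' @return Named numeric vector `c(failure = , success = )`, non-negative,
#'   summing to 1.
#' @export
predict_proba <- function(model, image) {
  stats::setNames(model_forward(model, image)$probs, MODEL_CLASSES)
}

#' Backbone feature vector for one rhythm image
#'
#' The backbone output with the dense head and decision layer removed:
#' the global-average-pooled feature vector (length 1280 for the
#' `efficientnet_b0_topology` backbone, `feature_dim` for `tiny_cnn`).
#'
#' @inheritParams predict_proba
#' @return Numeric feature vector.
#' @export
extract_features <- function(model, image) {
  model_forward(model, image)$feat
}

balanced_accuracy <- function(pred_idx, y_idx) {
  mean(vapply(1:2, function(k) {
    sel <- y_idx == k
    if (!any(sel)) return(NA_real_)
    mean(pred_idx[sel] == k)
  }, numeric(1L)), na.rm = TRUE)
}

#' Evaluate a model on a test set
#'
#' @param model A trained `possession_model`.
#' @param x_test List of image tensors.
#' @param y_test Labels (logical or `"failure"`/`"success"`).
#' @param split_id Optional identifier of the evaluation split.
#' @return Object of class `eval_report`: list with `balanced_accuracy`
#'   (mean of per-class recalls), `confusion` (2 x 2 counts laid out
#'   `[TP, FN; FP, TN]` with success as the positive class), `split_id`,
#'   `seed`, and the test labels.
#' @export
evaluate_model <- function(model, x_test, y_test, split_id = NA_integer_) {
  y <- to_y_idx(y_test)
  pred <- apply(model_predict_probs(model, x_test), 2L, which.max)
  report_from_predictions(pred, y, split_id, model$config$seed)
}

report_from_predictions <- function(pred_idx, y_idx, split_id = NA_integer_,
                                    seed = NA_integer_) {
  tp <- sum(pred_idx == 2L & y_idx == 2L)
  fn <- sum(pred_idx == 1L & y_idx == 2L)
  fp <- sum(pred_idx == 2L & y_idx == 1L)
  tn <- sum(pred_idx == 1L & y_idx == 1L)
  structure(list(
    balanced_accuracy = balanced_accuracy(pred_idx, y_idx),
    confusion = matrix(c(tp, fp, fn, tn), 2L, 2L,
                       dimnames = list(c("true_success", "true_failure"),
                                       c("pred_success", "pred_failure"))),
    split_id = split_id, seed = seed, n = length(y_idx),
    y = y_idx), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> split %s: balanced accuracy %.3f (n = %d)\n",
              x$split_id, x$balanced_accuracy, x$n))
  print(x$confusion)
  invisible(x)
}
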