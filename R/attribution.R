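#' Shapley-value attribution of one prediction
#'
#' Estimates Shapley values for the model's success probability with a
#' kernel-weighted local linear surrogate (KernelSHAP). Coalition features
#' are (player-row, channel) groups — 176 for an 11-row, 16-channel image —
#' rather than raw pixels, which keeps the regression exactly solvable at
#' desk scale. A masked feature is replaced by the corresponding rows of
#' the background image. The sum constraint
#' `base_value + sum(values) = f(x)` is eliminated analytically, so local
#' accuracy holds to solver precision.
#'
#' @param model A trained `possession_model`, or any function mapping an
#'   image tensor to a scalar output.
#' @param image The `11 x T x 16` tensor to explain.
#' @param background Reference tensor of the same shape, conventionally
#'   the elementwise mean over the training images (see
#'   [mean_background()]).
#' @param n_coalitions Number of coalitions sampled (default 4x the number
#'   of features); must be at least `features + 2`.
#' @param seed Integer seed for coalition sampling.
#' @return Array of the same shape as `image` (class `attribution_map`):
#'   each (row, channel) group's Shapley value spread uniformly over its
#'   `T` pixels, with attributes `base_value` (`f(background)`) and `fx`
#'   (`f(image)`).
#' @export
shapley_attribution <- function(model, image, background,
                                n_coalitions = NULL, seed = 1) {
  f <- if (is.function(model)) model else
    function(img) as.numeric(predict_proba(model, img)["success"])
  dm <- dim(image)
  stopifnot(length(dm) == 3L, all(dim(background) == dm))
  nr <- dm[1L]; Tlen <- dm[2L]; nc <- dm[3L]
  M <- nr * nc  # feature k <-> (row, channel): k = (channel-1)*nr + row
  if (is.null(n_coalitions)) n_coalitions <- 4L * M
  if (n_coalitions < M + 2L)
    stop(sprintf("n_coalitions (%d) must be at least features + 2 (%d)",
                 n_coalitions, M + 2L))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)

  f0 <- f(background)
  fx <- f(image)

  ## Coalition design: all singletons, all complements of singletons,
  ## then random coalitions with sizes drawn from the Shapley kernel.
  Z <- matrix(0L, n_coalitions, M)
  for (k in seq_len(M)) {
    Z[k, k] <- 1L
    Z[M + k, ] <- 1L
    Z[M + k, k] <- 0L
  }
  n_rand <- n_coalitions - 2L * M
  if (n_rand > 0L && M > 3L) {
    sizes <- 2:(M - 2L)
    pr <- (M - 1) / (sizes * (M - sizes))
    drawn <- sample(sizes, n_rand, replace = TRUE, prob = pr)
    for (i in seq_len(n_rand))
      Z[2L * M + i, sample.int(M, drawn[i])] <- 1L
  }
  sz <- rowSums(Z)
  keep <- sz > 0L & sz < M
  Z <- Z[keep, , drop = FALSE]
  sz <- sz[keep]
  w <- (M - 1) / (choose(M, sz) * sz * (M - sz))

  masked_image <- function(z) {
    img <- background
    on_idx <- which(z == 1L)
    rows <- ((on_idx - 1L) %% nr) + 1L
    chans <- ((on_idx - 1L) %/% nr) + 1L
    for (i in seq_along(on_idx))
      img[rows[i], , chans[i]] <- image[rows[i], , chans[i]]
    img
  }
  y <- if (is.function(model)) {
    apply(Z, 1L, function(z) f(masked_image(z)))
  } else {
    ## batched inference over coalition chunks
    imgs <- lapply(seq_len(nrow(Z)), function(i) masked_image(Z[i, ]))
    model_predict_probs(model, imgs)[2L, ]
  }
  y <- y - f0

  ## Constrained WLS: eliminate phi_M via sum(phi) = fx - f0.
  delta <- fx - f0
  Zt <- Z[, -M, drop = FALSE] - Z[, M]
  yt <- y - Z[, M] * delta
  A <- crossprod(Zt, Zt * w)
  b <- crossprod(Zt, yt * w)
  phi_rest <- tryCatch(solve(A, b),
                       error = function(e)
                         solve(A + diag(1e-10, ncol(A)), b))
  phi <- c(as.numeric(phi_rest), delta - sum(phi_rest))

  values <- array(0, dm)
  for (k in seq_len(M)) {
    r <- ((k - 1L) %% nr) + 1L
    cch <- ((k - 1L) %/% nr) + 1L
    values[r, , cch] <- phi[k] / Tlen
  }
  structure(values, base_value = f0, fx = fx, class = "attribution_map")
}

#' Elementwise mean background image
#'
#' @param images List of image tensors of identical shape.
#' @return Their elementwise mean — the masking baseline recommended for
#'   [shapley_attribution()].
#' @export
mean_background <- function(images) {
  Reduce(`+`, images) / length(images)
}

#' Aggregate attribution maps into per-metric percentage shares
#'
#' Restricts to the samples of the requested class (by default the
#' successes — possessions that reached the attacking zone), sums the
#' absolute Shapley values over samples, players and frames for each of
#' the 16 channels, and normalizes to percentages within each team's
#' eight metrics.
#'
#' @param maps List of [shapley_attribution()] maps.
#' @param labels Logical success labels, one per map.
#' @param class_filter `"success"` (default) or `"failure"`.
#' @return data.frame with `team_role` (`"attacking"`/`"defending"`),
#'   `metric`, and `share_pct`; shares sum to 100 within each team role.
#' @export
aggregate_by_metric <- function(maps, labels, class_filter = "success") {
  stopifnot(length(maps) == length(labels),
            class_filter %in% c("success", "failure"))
  sel <- if (class_filter == "success") which(labels) else which(!labels)
  if (!length(sel))
    stop("no sample passes the class filter '", class_filter, "'")
  totals <- numeric(16L)
  for (i in sel)
    totals <- totals + vapply(1:16, function(k) sum(abs(maps[[i]][, , k])),
                              numeric(1L))
  out <- data.frame(
    team_role = rep(c("attacking", "defending"), each = 8L),
    metric = rep(rhythm_metrics(), 2L),
    abs_total = totals)
  out$share_pct <- with(out, stats::ave(abs_total, team_role,
                                        FUN = function(v) 100 * v / sum(v)))
  out$abs_total <- NULL
  out
}

#' Horizontal bar chart of per-metric contribution shares
#'
#' @param contrib An [aggregate_by_metric()] table.
#' @param team_role Which team's shares to draw.
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_metric_contribution <- function(contrib, team_role = "defending", ...) {
  d <- contrib[contrib$team_role == team_role, ]
  d <- d[order(d$share_pct), ]
  graphics::barplot(d$share_pct, names.arg = d$metric, horiz = TRUE,
                    las = 1, xlab = "share of |Shapley| values (%)",
                    main = paste(team_role, "team"), ...)
}
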