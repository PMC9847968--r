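#' Draw a group-aware train/validation/test split
#'
#' Splits group identifiers (half-matches; a 10-match dataset yields 20)
#' into disjoint test, validation and training sets of whole groups, so
#' that every possession interval of a half-match stays on one side.
#'
#' @param groups Vector of group ids, one per sample.
#' @param n_test Number of test groups (default 6).
#' @param n_val Number of validation groups drawn from the remaining
#'   groups (default 4).
#' @param seed Integer seed.
#' @return List with `test_groups`, `val_groups`, `train_groups` and the
#'   corresponding sample index vectors `test`, `val`, `train`.
#' @export
group_split <- function(groups, n_test = 6, n_val = 4, seed = 1) {
  ids <- unique(groups)
  if (length(ids) < n_test + n_val + 1L)
    stop("not enough groups for the requested split")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  test_g <- sample(ids, n_test)
  rest <- setdiff(ids, test_g)
  val_g <- sample(rest, n_val)
  train_g <- setdiff(rest, val_g)
  list(test_groups = test_g, val_groups = val_g, train_groups = train_g,
       test = which(groups %in% test_g),
       val = which(groups %in% val_g),
       train = which(groups %in% train_g))
}

default_grid <- function(config) {
  data.frame(lr = c(1e-3, 2e-3), head_width = config$head_width)
}

#' Repeated group-aware evaluation
#'
#' Runs the full protocol `n_rounds` times. Each round draws a fresh
#' group split (6 test groups, the rest split into training and
#' validation groups), fits the per-channel [fit_normalizer()] on the
#' round's training images only, grid-searches the (learning rate x head
#' width) grid by validation balanced accuracy, and evaluates the
#' selected model on the held-out test groups.
#'
#' @param images List of raw rhythm tensors (see [bpi_rhythm_raw()]) when
#'   `normalize = TRUE`, else already-normalized tensors.
#' @param labels Logical success labels, one per image.
#' @param groups Group ids, one per image.
#' @param config A [model_config()]; per-round seeds are derived from
#'   `config$seed`.
#' @param n_rounds Number of evaluation rounds (default 10).
#' @param grid data.frame of hyperparameter candidates with columns `lr`
#'   and `head_width`; defaults to learning rates 1e-3 and 2e-3 at the
#'   configured head width.
#' @param n_test,n_val Groups held out for test and validation each round.
#' @param normalize Fit and apply the min-max normalizer per round
#'   (default `TRUE`; prevents test-set leakage through pixel scaling).
#' @return List of `n_rounds` [evaluate_model()] reports with distinct
#'   `split_id`s.
#' @export
repeated_group_eval <- function(images, labels, groups,
                                config = model_config("tiny_cnn"),
                                n_rounds = 10, grid = default_grid(config),
                                n_test = 6, n_val = 4, normalize = TRUE) {
  stopifnot(length(images) == length(labels),
            length(images) == length(groups))
  reports <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    rseed <- config$seed + 131L * r
    sp <- group_split(groups, n_test, n_val, seed = rseed)
    xs <- images
    if (normalize) {
      norm <- fit_normalizer(images[sp$train])
      xs <- lapply(images, assemble_image, normalizer = norm)
    }
    best <- NULL
    for (gi in seq_len(nrow(grid))) {
      cfg <- config
      cfg$lr <- grid$lr[gi]
      cfg$head_width <- as.integer(grid$head_width[gi])
      cfg$seed <- rseed + gi
      m <- fit_model(xs[sp$train], labels[sp$train],
                     xs[sp$val], labels[sp$val], cfg)
      if (is.null(best) ||
          m$val_balanced_accuracy > best$val_balanced_accuracy)
        best <- m
    }
    reports[[r]] <- evaluate_model(best, xs[sp$test], labels[sp$test],
                                   split_id = r)
    reports[[r]]$seed <- rseed
    reports[[r]]$test_groups <- sp$test_groups
  }
  reports
}

#' Random-classifier baseline reports
#'
#' For each evaluation report, simulates a classifier that picks each
#' class with probability one half on the same test labels, giving the
#' paired baseline for [wilcoxon_vs_random()].
#'
#' @param reports List of `eval_report`s (their stored test labels are
#'   reused).
#' @param seed Integer seed.
#' @return List of `eval_report`s of the random classifier.
#' @export
random_baseline_reports <- function(reports, seed = 1) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  lapply(reports, function(rep) {
    pred <- sample(1:2, length(rep$y), replace = TRUE)
    report_from_predictions(pred, rep$y, rep$split_id, seed)
  })
}

#' One-sided exact Wilcoxon signed-rank test against a paired baseline
#'
#' Tests whether the per-round balanced accuracies of the model exceed
#' those of the paired baseline. Zero differences are dropped; tied
#' absolute differences receive average ranks; the null distribution of
#' the positive-rank sum is enumerated exactly over all sign assignments
#' (for up to 30 non-zero pairs; a normal approximation applies beyond).
#' With all pairs strictly positive over n rounds the p-value is
#' `1 / 2^n`. When every difference is zero the test is degenerate and
#' p = 1.
#'
#' @param reports,baseline_reports Paired lists of `eval_report`s, or
#'   numeric vectors of balanced accuracies.
#' @return One-sided p-value for "model better than baseline".
#' @export
wilcoxon_vs_random <- function(reports, baseline_reports) {
  ba <- function(x) if (is.numeric(x)) x else
    vapply(x, `[[`, numeric(1L), "balanced_accuracy")
  x <- ba(reports); y <- ba(baseline_reports)
  stopifnot(length(x) == length(y))
  exact_signed_rank_p(x - y)
}

## P(W >= observed positive-rank sum) under random signs.
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n > 30L) {  # normal approximation with tie-corrected variance
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4
    return(stats::pnorm((W - mu) / sqrt(sigma2), lower.tail = FALSE))
  }
  ## Generating-function enumeration on doubled ranks (integers even
  ## under average-rank ties).
  m <- as.integer(round(2 * r))
  counts <- numeric(sum(m) + 1L)  # index k+1 holds #assignments with sum k
  counts[1L] <- 1
  for (mi in m) {
    shifted <- c(numeric(mi), counts[seq_len(length(counts) - mi)])
    counts <- counts + shifted
  }
  obs <- as.integer(round(2 * W))
  sum(counts[(obs + 1L):length(counts)]) / 2^n
}
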