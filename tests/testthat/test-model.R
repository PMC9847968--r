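small_cfg <- function(epochs = 30, patience = 10, ...) {
  model_config("tiny_cnn", epochs = epochs, patience = patience, seed = 7,
               ...)
}

test_that("probabilities are a softmax pair and features are deterministic", {
  m <- possession_model(small_cfg())
  x <- array(runif(11 * 25 * 16), c(11, 25, 16))
  p <- predict_proba(m, x)
  expect_named(p, c("failure", "success"))
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_identical(extract_features(m, x), extract_features(m, x))
  expect_length(extract_features(m, x), 32L)
})

test_that("the efficientnet-b0-style backbone yields 1280-d features", {
  m <- possession_model(model_config("efficientnet_b0_topology"))
  x <- array(runif(11 * 25 * 16), c(11, 25, 16))
  expect_length(extract_features(m, x), 1280L)
  p <- predict_proba(m, x)
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("training recovers a linearly separable planted signal", {
  d <- planted_images(n_per_class = 40, shift = 1.5, seed = 31)
  norm <- fit_normalizer(d$x[1:60])
  xs <- lapply(d$x, assemble_image, normalizer = norm)
  m <- fit_model(xs[1:60], d$y[1:60], xs[61:70], d$y[61:70], small_cfg())
  train_rep <- evaluate_model(m, xs[1:60], d$y[1:60])
  expect_gte(train_rep$balanced_accuracy, 0.95)
  expect_gte(evaluate_model(m, xs[71:80], d$y[71:80])$balanced_accuracy,
             0.9)
})

test_that("training is deterministic under a fixed seed", {
  d <- planted_images(n_per_class = 12, seed = 33)
  cfg <- small_cfg(epochs = 3, patience = 3)
  m1 <- fit_model(d$x[1:16], d$y[1:16], d$x[17:24], d$y[17:24], cfg)
  m2 <- fit_model(d$x[1:16], d$y[1:16], d$x[17:24], d$y[17:24], cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("single-class training sets are rejected", {
  d <- planted_images(n_per_class = 6, seed = 34)
  keep <- which(d$y)
  expect_error(fit_model(d$x[keep], d$y[keep], d$x, d$y, small_cfg()),
               "single class")
})

test_that("evaluation reports balanced accuracy and a conserving confusion", {
  m <- list()  # predictions fed directly through the internal helper
  rep1 <- passrhythm:::report_from_predictions(
    c(2L, 2L, 1L, 1L), c(2L, 2L, 1L, 1L))
  expect_equal(rep1$balanced_accuracy, 1)
  expect_equal(unname(rep1$confusion), rbind(c(2, 0), c(0, 2)))

  rep2 <- passrhythm:::report_from_predictions(
    rep(2L, 10), rep(c(2L, 1L), each = 5))  # all-success predictor
  expect_equal(rep2$balanced_accuracy, 0.5)
  expect_equal(sum(rep2$confusion), 10)
  expect_equal(unname(rep2$confusion), rbind(c(5, 0), c(5, 0)))
})

test_that("group splits keep every group's samples on one side", {
  groups <- rep(1:20, each = 5)
  sp <- group_split(groups, n_test = 6, n_val = 4, seed = 3)
  expect_length(sp$test_groups, 6L)
  expect_length(intersect(sp$test_groups, sp$val_groups), 0L)
  expect_length(intersect(sp$test_groups, sp$train_groups), 0L)
  expect_setequal(c(sp$test, sp$val, sp$train), seq_along(groups))
  expect_setequal(unique(groups[sp$test]), sp$test_groups)
  expect_error(group_split(1:5, n_test = 6), "not enough groups")
})

test_that("repeated rounds use distinct leak-free splits", {
  d <- planted_images(n_per_class = 30, shift = 1.5, seed = 35)
  cfg <- small_cfg(epochs = 4, patience = 4)
  reps <- repeated_group_eval(d$x, d$y, d$groups, cfg, n_rounds = 3,
                              grid = data.frame(lr = 1e-3,
                                                head_width = 32),
                              normalize = FALSE)
  expect_length(reps, 3L)
  expect_equal(sapply(reps, `[[`, "split_id"), 1:3)
  tg <- lapply(reps, `[[`, "test_groups")
  expect_false(identical(tg[[1]], tg[[2]]))
})

test_that("the exact signed-rank test matches enumeration and wilcox.test", {
  # ten rounds all strictly better than baseline: p = 1 / 2^10
  x <- seq(0.7, 0.9, length.out = 10)
  y <- x - runif(10, 0.01, 0.1)
  expect_equal(wilcoxon_vs_random(x, y), 1 / 1024)
  expect_equal(wilcoxon_vs_random(x, y),
               wilcox.test(x, y, paired = TRUE, exact = TRUE,
                           alternative = "greater")$p.value)

  # degenerate: identical pairs give p = 1
  expect_equal(wilcoxon_vs_random(x, x), 1)

  # agreement with wilcox.test on tie-free mixed-sign draws
  set.seed(44)
  for (i in 1:10) {
    a <- runif(8); b <- runif(8)
    expect_equal(wilcoxon_vs_random(a, b),
                 wilcox.test(a, b, paired = TRUE, exact = TRUE,
                             alternative = "greater")$p.value)
  }

  # swapping the pairing flips the one-sided tail
  a <- c(0.8, 0.7, 0.9, 0.6, 0.75); b <- a - c(0.1, 0.05, 0.2, 0.02, 0.07)
  p_fwd <- wilcoxon_vs_random(a, b)
  p_rev <- wilcoxon_vs_random(b, a)
  expect_lt(p_fwd, 0.05)
  expect_gt(p_rev, 0.95)
})

test_that("random baselines pair with reports and hover near chance", {
  reps <- lapply(1:6, function(i)
    passrhythm:::report_from_predictions(
      rep(c(1L, 2L), 25), rep(c(2L, 1L), each = 25), split_id = i))
  base <- random_baseline_reports(reps, seed = 5)
  expect_length(base, 6L)
  bas <- sapply(base, `[[`, "balanced_accuracy")
  expect_true(all(bas > 0.2 & bas < 0.8))
  expect_identical(base, random_baseline_reports(reps, seed = 5))
})
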