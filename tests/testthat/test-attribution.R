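dims <- c(11, 6, 16)
nfeat <- dims[1] * dims[3]

test_that("a linear model recovers closed-form Shapley values", {
  set.seed(51)
  w <- array(rnorm(prod(dims), sd = 0.2), dims)
  linmod <- function(img) sum(w * img)
  x <- array(runif(prod(dims)), dims)
  bg <- array(runif(prod(dims)), dims)
  map <- shapley_attribution(linmod, x, bg, n_coalitions = 3 * nfeat,
                             seed = 2)
  # Shapley value of group k for a linear model: sum of w * (x - bg) there
  for (k in sample(nfeat, 12)) {
    r <- (k - 1) %% 11 + 1; ch <- (k - 1) %/% 11 + 1
    expect_equal(sum(map[r, , ch]),
                 sum(w[r, , ch] * (x[r, , ch] - bg[r, , ch])),
                 tolerance = 1e-6)
  }
  expect_equal(attr(map, "base_value"), linmod(bg), tolerance = 1e-9)
})

test_that("a constant model receives zero attributions", {
  x <- array(runif(prod(dims)), dims)
  bg <- array(runif(prod(dims)), dims)
  map <- shapley_attribution(function(img) 0.42, x, bg,
                             n_coalitions = 2 * nfeat, seed = 3)
  expect_lt(max(abs(map)), 1e-8)
})

test_that("attribution is deterministic given the seed and needs enough coalitions", {
  set.seed(52)
  w <- array(rnorm(prod(dims), sd = 0.1), dims)
  f <- function(img) tanh(sum(w * img))
  x <- array(runif(prod(dims)), dims)
  bg <- array(0.5, dims)
  m1 <- shapley_attribution(f, x, bg, n_coalitions = 2 * nfeat, seed = 9)
  m2 <- shapley_attribution(f, x, bg, n_coalitions = 2 * nfeat, seed = 9)
  expect_identical(m1, m2)
  expect_error(shapley_attribution(f, x, bg, n_coalitions = 10),
               "at least")
})

test_that("local accuracy holds for the trained network", {
  d <- planted_images(n_per_class = 20, shift = 1.5, Tlen = 6, seed = 53)
  cfg <- model_config("tiny_cnn", epochs = 10, patience = 10, seed = 7)
  m <- fit_model(d$x[1:24], d$y[1:24], d$x[25:32], d$y[25:32], cfg)
  bg <- mean_background(d$x[1:24])
  for (i in 33:35) {
    map <- shapley_attribution(m, d$x[[i]], bg,
                               n_coalitions = 4 * nfeat, seed = i)
    fx <- as.numeric(predict_proba(m, d$x[[i]])["success"])
    expect_lt(abs(attr(map, "base_value") + sum(map) - fx), 1e-3)
    expect_equal(attr(map, "fx"), fx, tolerance = 1e-9)
  }
})

test_that("aggregation concentrates, normalizes, and scales correctly", {
  map1 <- array(0, dims)
  map1[, , 5] <- 0.3   # all attacking mass on one channel
  map1[, , 12] <- -0.2 # defending mass on one channel (sign ignored)
  contrib <- aggregate_by_metric(list(map1), labels = TRUE)
  atk <- contrib[contrib$team_role == "attacking", ]
  expect_equal(atk$share_pct[atk$metric == "global_efficiency"], 100)
  expect_equal(sum(atk$share_pct), 100)
  def <- contrib[contrib$team_role == "defending", ]
  expect_equal(def$share_pct[def$metric == "entropy"], 100)

  # duplicating samples leaves percentages unchanged
  set.seed(54)
  maps <- lapply(1:3, function(i) array(rnorm(prod(dims)), dims))
  c1 <- aggregate_by_metric(maps, labels = rep(TRUE, 3))
  c2 <- aggregate_by_metric(c(maps, maps), labels = rep(TRUE, 6))
  expect_equal(c1$share_pct, c2$share_pct)

  # class filter selects, and empty selections error
  c3 <- aggregate_by_metric(maps, labels = c(TRUE, FALSE, FALSE),
                            class_filter = "failure")
  expect_equal(sum(c3$share_pct), 200)  # 100 per team role
  expect_error(aggregate_by_metric(maps, labels = rep(FALSE, 3)),
               "no sample")
})

test_that("channels made identical by construction share credit equally", {
  set.seed(55)
  w <- array(0, dims)
  w[, , 4] <- 0.1
  w[, , 6] <- 0.1  # two channels with identical roles
  f <- function(img) sum(w * img)
  bg <- array(0.5, dims)
  maps <- lapply(1:4, function(i) {
    x <- array(runif(prod(dims)), dims)
    x[, , 6] <- x[, , 4]  # identical content too
    shapley_attribution(f, x, bg, n_coalitions = 3 * nfeat, seed = i)
  })
  contrib <- aggregate_by_metric(maps, labels = rep(TRUE, 4))
  atk <- contrib[contrib$team_role == "attacking", ]
  s4 <- atk$share_pct[atk$metric == rhythm_metrics()[4]]
  s6 <- atk$share_pct[atk$metric == rhythm_metrics()[6]]
  expect_lt(abs(s4 - s6) / max(s4, s6), 0.05)
})
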