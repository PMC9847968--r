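metric_tab <- function(values, players, cols, metric = "entropy") {
  data.frame(col = cols, frame = cols - 1L, team = "A",
             player = players, metric = metric, value = values)
}

test_that("channels place player i at row i, frame j at column j", {
  tab <- rbind(metric_tab(rep(1, 4), rep("0", 4), 1:4),
               metric_tab(rep(2, 4), rep("1", 4), 1:4))
  F <- build_channel(tab, "entropy")
  expect_equal(dim(F), c(11L, 4L))
  expect_equal(unname(F[1, ]), rep(1, 4))
  expect_equal(unname(F[2, ]), rep(2, 4))
  expect_equal(unname(F[3:11, ]), matrix(0, 9, 4))  # absent players zero
  expect_error(build_channel(tab, "nonsense"), "unknown metric")
  expect_error(build_channel(tab, "entropy", T = 2), "beyond")
})

test_that("a full FETW yields the documented tensor shape", {
  poss <- data.frame(frame = 0:359, team = "A")
  ds <- toy_tracking(n_frames = 360, n_players = 3, possession = poss)
  ds$rosters <- list(A = 0:2, B = 0:2)
  bpis <- windowed_bpis(ds)
  x <- bpi_rhythm_raw(ds, bpis[1, ], graph_rate = 5)
  expect_equal(dim(x), c(11L, 25L, 16L))  # 5 s FETW at 5 Hz
  x30 <- bpi_rhythm_raw(ds, bpis[1, ], graph_rate = 30)
  expect_equal(dim(x30), c(11L, 150L, 16L))
  expect_equal(attr(x, "channel_order"), channel_names())
})

test_that("normalizer records per-channel extrema and is order-invariant", {
  set.seed(21)
  imgs <- lapply(1:5, function(i) array(runif(11 * 6 * 16, 0, i),
                                        c(11, 6, 16)))
  n1 <- fit_normalizer(imgs)
  expect_equal(n1$min, sapply(1:16, function(k)
    min(sapply(imgs, function(x) min(x[, , k])))))
  n2 <- fit_normalizer(rev(imgs))
  expect_equal(n1, n2)
  expect_equal(fit_normalizer(imgs), fit_normalizer(imgs))  # idempotent

  one <- array(rep(0:8, length.out = 11 * 6 * 16), c(11, 6, 16))
  nf <- fit_normalizer(one)
  expect_equal(nf$min, rep(0, 16))
  expect_equal(nf$max, rep(8, 16))
})

test_that("assembly min-max scales, clips, and flattens degenerate channels", {
  set.seed(22)
  train <- lapply(1:4, function(i) array(runif(11 * 6 * 16), c(11, 6, 16)))
  for (i in seq_along(train)) train[[i]][, , 3] <- 5  # constant channel
  norm <- fit_normalizer(train)
  test <- array(runif(11 * 6 * 16), c(11, 6, 16))
  test[1, 1, 1] <- 2 * norm$max[1]   # out-of-range pixel
  img <- assemble_image(test, norm)
  expect_equal(dim(img)[3], 16L)
  expect_true(all(img >= 0 & img <= 1))
  expect_equal(img[1, 1, 1], 1)               # clipped to 1
  expect_equal(unname(img[, , 3]), matrix(0, 11, 6))  # degenerate -> 0

  chans <- stats::setNames(
    lapply(1:16, function(k) test[, , k]), channel_names())
  expect_equal(assemble_image(chans, norm), img, ignore_attr = TRUE)
  expect_error(assemble_image(chans[-1], norm), "missing channel")
})

test_that("pixels are monotone in their raw metric value", {
  set.seed(23)
  train <- lapply(1:4, function(i) array(runif(11 * 6 * 16), c(11, 6, 16)))
  norm <- fit_normalizer(train)
  x <- train[[1]]
  base <- assemble_image(x, norm)
  for (delta in c(0.05, 0.2, 3)) {
    x2 <- x
    x2[4, 2, 7] <- x2[4, 2, 7] + delta
    expect_gte(assemble_image(x2, norm)[4, 2, 7], base[4, 2, 7])
  }
})

test_that("image rows track roster players across all channels", {
  poss <- data.frame(frame = 0:359, team = "A")
  ds <- toy_tracking(n_frames = 360, n_players = 4, possession = poss)
  ds$rosters <- list(A = 0:3, B = 0:3)
  # plant a per-player spike: isolate player 2 of team B by marking
  bpis <- windowed_bpis(ds)
  x <- bpi_rhythm_raw(ds, bpis[1, ], graph_rate = 5)
  # rows 5..11 must be zero for every channel (roster has 4 players)
  for (k in 1:16)
    expect_equal(unname(x[5:11, , k]), matrix(0, 7, dim(x)[2]))
  # attacking pagerank rows 1..4 are nonzero (pagerank > 0 always)
  expect_true(all(x[1:4, , which(channel_names() ==
                                   "attacking:pagerank")] > 0))
})

test_that("single channels export as grayscale PNG", {
  skip_if_not_installed("png")
  F <- matrix(runif(11 * 6), 11, 6)
  path <- withr::local_tempfile(fileext = ".png")
  write_channel_png(F, path)
  expect_true(file.exists(path))
  expect_equal(dim(png::readPNG(path)), c(11, 6))
})
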