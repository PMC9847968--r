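test_that("tracking CSV round-trips through write and read", {
  ds <- toy_tracking(n_frames = 2, n_players = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking(ds, path)
  ds2 <- read_tracking(path, rate = ds$rate)
  expect_equal(n_frames(ds2), 2L)
  expect_equal(sort(unique(ds2$players$team)), c("A", "B"))
  expect_equal(ds2$players[c("frame", "team", "player", "x", "y")],
               ds$players[c("frame", "team", "player", "x", "y")])
  expect_equal(ds2$ball, ds$ball)
  expect_equal(ds2$possession, ds$possession)
})

test_that("schema violations are format errors", {
  ds <- toy_tracking(n_frames = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking(ds, path)
  raw <- read.csv(path, comment.char = "#")
  raw$x <- NULL
  write.csv(raw, path, row.names = FALSE)
  expect_error(read_tracking(path, rate = 30), "missing required column")
})

test_that("out-of-pitch coordinates are clipped with a message", {
  players <- data.frame(frame = 0, team = "A", player = 0, x = 120, y = -3)
  ball <- data.frame(frame = 0, x = 50, y = 30)
  poss <- data.frame(frame = 0, team = "A")
  expect_message(ds <- tracking_dataset(players, ball, poss), "clipping")
  expect_equal(ds$players$x, 105)
  expect_equal(ds$players$y, 0)
})

test_that("attack-direction normalization reflects only when needed", {
  ds <- toy_tracking()  # ball drifts towards +x under A's possession
  expect_equal(normalize_attack_direction(ds, "A"), ds)

  refl <- normalize_attack_direction(ds, "A", direction = "-x")
  expect_equal(refl$ball$x, 105 - ds$ball$x)
  expect_equal(refl$players$y, 68 - ds$players$y)

  # ball at x = 10 on a 105 m pitch lands at 95 after reflection
  ds$ball$x[1] <- 10
  expect_equal(normalize_attack_direction(ds, "A", "-x")$ball$x[1], 95)

  expect_error(normalize_attack_direction(ds, "C"), "unknown team")
})

test_that("normalization is idempotent and inference follows ball drift", {
  ds <- toy_tracking()
  ds$ball$x <- rev(ds$ball$x)  # now A's possession drifts towards -x
  once <- normalize_attack_direction(ds, "A")
  expect_false(isTRUE(all.equal(once$ball$x, ds$ball$x)))
  twice <- normalize_attack_direction(once, "A")
  expect_equal(twice, once)
})

test_that("reflection preserves all pairwise inter-player distances", {
  ds <- toy_tracking(n_frames = 3, n_players = 4)
  refl <- normalize_attack_direction(ds, "A", "-x")
  for (f in 0:2) {
    p1 <- ds$players[ds$players$frame == f, c("x", "y")]
    p2 <- refl$players[refl$players$frame == f, c("x", "y")]
    expect_lt(max(abs(dist(p1) - dist(p2))), 1e-9)
  }
})

test_that("resampling decimates frames and follows possession labels", {
  poss <- data.frame(frame = 0:149, team = rep(c("A", "B"), each = 75))
  ds <- toy_tracking(n_frames = 150, possession = poss)
  half <- resample_tracking(ds, 15)
  expect_equal(half$rate, 15)
  expect_equal(n_frames(half), 75L)
  expect_equal(half$possession$team, c(rep("A", 38), rep("B", 37)))
  expect_equal(resample_tracking(ds, 30), ds)
  expect_error(resample_tracking(ds, 20), "does not divide")
})

test_that("short player occlusion gaps are carried forward", {
  ds <- toy_tracking(n_frames = 10)
  drop <- ds$players$team == "A" & ds$players$player == 0 &
    ds$players$frame %in% 3:5
  players <- ds$players[!drop, ]
  ds2 <- tracking_dataset(players, ds$ball, ds$possession, rate = 30)
  got <- ds2$players[ds2$players$team == "A" & ds2$players$player == 0, ]
  expect_equal(got$frame, 0:9)  # gap of 3 frames (< 1 s) filled
  expect_equal(got$x[4:6], rep(got$x[3], 3))  # carried forward, not moved
})
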