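test_that("small point sets triangulate per the empty-circumcircle rule", {
  tri <- rbind(c(0, 0), c(10, 0), c(5, 8))
  expect_equal(nrow(delaunay_edges(tri)), 3L)

  quad <- rbind(c(0, 0), c(4, 0), c(5, 3), c(1, 4))
  e <- delaunay_edges(quad)
  expect_equal(nrow(e), 5L)  # 4 hull edges + 1 diagonal
  expect_equal(edge_key(e), edge_key(oracle_delaunay(quad)))

  expect_equal(unname(delaunay_edges(rbind(c(0, 0), c(3, 3)))),
               matrix(c(1L, 2L), 1))
  expect_equal(nrow(delaunay_edges(rbind(c(1, 1)))), 0L)
})

test_that("degenerate point sets fall back without failing", {
  # collinear points chain between coordinate-sorted neighbours
  line <- cbind(c(3, 0, 9, 6), 0)
  e <- delaunay_edges(line)
  expect_equal(edge_key(e), c("1-2", "1-4", "3-4"))
  # coincident points are jittered deterministically, twice alike
  dup <- rbind(c(1, 1), c(1, 1), c(5, 5), c(2, 7))
  expect_equal(delaunay_edges(dup), delaunay_edges(dup))
})

test_that("triangulation matches the brute-force oracle on random sets", {
  set.seed(41)
  for (i in 1:120) {
    n <- sample(3:8, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 68))
    expect_equal(edge_key(delaunay_edges(pts)),
                 edge_key(oracle_delaunay(pts)),
                 info = paste("draw", i))
  }
})

test_that("marking uses an inclusive 0.5 m radius", {
  tp <- rbind("0" = c(0, 0), "1" = c(10, 0))
  expect_equal(marked_players(tp, rbind(c(0, 0.5))), "0")
  expect_equal(marked_players(tp, rbind(c(0, 0.51))), character())
  expect_equal(marked_players(tp, tp[0, , drop = FALSE]), character())
  expect_equal(marked_players(tp, NULL), character())
})

test_that("marked players lose all incident edges but stay vertices", {
  tp <- rbind("0" = c(0, 0), "1" = c(10, 0), "2" = c(5, 8))
  g0 <- build_frame_graph(tp, NULL)
  expect_equal(nrow(g0$edges), 3L)

  g1 <- build_frame_graph(tp, rbind(c(0.3, 0)))  # opponent marks player 0
  expect_equal(g1$marked, "0")
  expect_equal(nrow(g1$edges), 1L)
  expect_setequal(as.vector(g1$edges), c("1", "2"))
  expect_equal(g1$vertices, c("0", "1", "2"))
  expect_equal(sum(pass_adjacency(g1)["0", ]), 0)

  g2 <- build_frame_graph(tp, tp)  # everyone marked
  expect_equal(nrow(g2$edges), 0L)
  expect_equal(length(g2$vertices), 3L)
})

test_that("growing the marking radius never adds edges", {
  set.seed(7)
  tp <- cbind(runif(8, 0, 40), runif(8, 0, 30))
  rownames(tp) <- 0:7
  op <- cbind(runif(8, 0, 40), runif(8, 0, 30))
  prev <- Inf
  for (r in c(0, 0.5, 1, 2, 5, 10)) {
    m <- nrow(build_frame_graph(tp, op, marking_params(r))$edges)
    expect_lte(m, prev)
    prev <- m
  }
})

test_that("graph construction is invariant under rigid motions", {
  set.seed(8)
  tp <- cbind(runif(9, 10, 60), runif(9, 10, 50))
  rownames(tp) <- 0:8
  op <- cbind(runif(9, 10, 60), runif(9, 10, 50))
  base <- build_frame_graph(tp, op)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  move <- function(m) sweep(m %*% R, 2, c(-15, 22), "+")
  tp2 <- move(tp); rownames(tp2) <- rownames(tp)
  rot <- build_frame_graph(tp2, move(op))
  expect_equal(base$edges, rot$edges)
  expect_equal(base$marked, rot$marked)
})

test_that("temporal sequences sample the window at the graph rate", {
  poss <- data.frame(frame = 0:299, team = "A")
  ds <- toy_tracking(n_frames = 300, n_players = 4, possession = poss)
  gs <- build_sequence(ds, c(0L, 150L), "A")
  expect_length(gs, 150L)  # 5 s at 30 Hz
  expect_length(build_sequence(ds, c(10L, 10L), "A"), 0L)
  half <- build_sequence(ds, c(0L, 150L), "A", graph_rate = 15)
  expect_length(half, 75L)
  expect_equal(half[[2]]$frame, gs[[3]]$frame)
})
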