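star <- function(k = 4) {
  A <- matrix(0, k + 1, k + 1)
  A[1, 2:(k + 1)] <- 1; A[2:(k + 1), 1] <- 1
  A
}
path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
triangle <- matrix(1, 3, 3) - diag(3)
cycle4 <- local({
  A <- matrix(0, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; A[i, j] <- 1; A[j, i] <- 1 }
  A
})

test_that("betweenness matches hand-derived values on canonical graphs", {
  b <- betweenness_centrality(star())
  expect_equal(b[[1]], 1)           # hub carries all 12 ordered leaf pairs
  expect_equal(unname(b[-1]), rep(0, 4))
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))
  expect_equal(unname(betweenness_centrality(matrix(0, 2, 2))), c(0, 0))
})

test_that("eccentricity is component-restricted", {
  expect_equal(unname(vertex_eccentricity(path3)), c(2, 1, 2))
  two_edges <- rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                     c(0, 0, 0, 1), c(0, 0, 1, 0))
  expect_equal(unname(vertex_eccentricity(two_edges)), rep(1, 4))
  expect_equal(unname(vertex_eccentricity(diag(0, 3))), rep(0, 3))
})

test_that("efficiencies and vulnerability follow their definitions", {
  K5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(unname(global_efficiency(K5)), rep(1, 5))
  expect_equal(global_efficiency(path3)[[1]], 0.75)  # (1 + 1/2) / 2
  expect_equal(unname(global_efficiency(diag(0, 4))), rep(0, 4))

  expect_equal(unname(local_efficiency(triangle)), rep(1, 3))
  expect_equal(local_efficiency(star())[[1]], 0)   # leaves unconnected
  expect_equal(local_efficiency(path3)[[1]], 0)    # degree-1 vertex

  expect_equal(unname(vertex_vulnerability(triangle)), rep(0, 3))
  expect_equal(vertex_vulnerability(star())[[1]], 1)  # E = 1, Eloc = 0
  expect_equal(unname(vertex_vulnerability(diag(0, 3))), rep(0, 3))
})

test_that("clustering counts triangles", {
  expect_equal(unname(clustering_coefficient(triangle)), rep(1, 3))
  expect_equal(clustering_coefficient(star())[[1]], 0)
  K4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(unname(clustering_coefficient(K4)), rep(1, 4))
})

test_that("walk entropy reduces to log degree at h = 1", {
  h1 <- metric_config(h = 1)
  expect_equal(unname(walk_entropy(cycle4, h1)), rep(log(2), 4))
  set.seed(3)
  A <- random_adjacency(7, 0.5)
  expect_equal(unname(walk_entropy(A, h1)),
               ifelse(rowSums(A) > 0, log(rowSums(A)), 0))
  expect_equal(unname(walk_entropy(diag(0, 3), metric_config(h = 3))),
               rep(0, 3))
})

test_that("pagerank hits symmetry fixed points and always sums to one", {
  expect_equal(unname(pagerank_centrality(cycle4)), rep(0.25, 4))
  expect_equal(unname(pagerank_centrality(diag(0, 5))), rep(0.2, 5))
  set.seed(4)
  for (i in 1:20) {
    p <- pagerank_centrality(random_adjacency(sample(2:9, 1), 0.4))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p > 0))
  }
  tiny <- metric_config(pagerank_max_iter = 2, pagerank_tol = 1e-300)
  expect_error(pagerank_centrality(path3, tiny), "converge")
})

test_that("all eight metrics match their brute-force oracles", {
  set.seed(11)
  cfg <- metric_config(h = 3)
  for (i in 1:150) {
    n <- sample(2:8, 1)
    A <- random_adjacency(n, runif(1, 0.2, 0.8))
    m <- compute_all_metrics(A, cfg)
    expect_equal(m$betweenness, oracle_betweenness(A), tolerance = 1e-10)
    expect_equal(unname(m$eccentricity), oracle_eccentricity(A))
    expect_equal(m$global_efficiency, oracle_global_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(m$local_efficiency, oracle_local_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(m$vulnerability, oracle_vulnerability(A),
                 tolerance = 1e-12)
    expect_equal(m$clustering, oracle_clustering(A), tolerance = 1e-12)
    expect_equal(m$entropy, oracle_walk_entropy(A, 3), tolerance = 1e-10)
    expect_equal(m$pagerank, oracle_pagerank(A), tolerance = 1e-7)
  }
})

test_that("metrics respect declared ranges and vertex relabeling", {
  set.seed(12)
  for (i in 1:30) {
    n <- sample(3:9, 1)
    A <- random_adjacency(n, 0.5)
    m <- compute_all_metrics(A)
    expect_true(all(m$betweenness >= 0 & m$betweenness <= 1))
    expect_true(all(m$clustering >= 0 & m$clustering <= 1))
    expect_true(all(m$global_efficiency >= 0 & m$global_efficiency <= 1))
    expect_true(all(m$local_efficiency >= 0 & m$local_efficiency <= 1))
    expect_true(all(m$entropy >= 0))
    expect_equal(sum(m$pagerank), 1, tolerance = 1e-9)

    perm <- sample(n)
    mp <- compute_all_metrics(A[perm, perm])
    for (col in rhythm_metrics())
      expect_equal(mp[[col]], m[[col]][perm], tolerance = 1e-8)
  }
})

test_that("metric computation is deterministic", {
  set.seed(13)
  A <- random_adjacency(8, 0.5)
  expect_identical(compute_all_metrics(A), compute_all_metrics(A))
})
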