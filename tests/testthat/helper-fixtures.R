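# Deterministic fixtures built in code, plus a memoized synthetic study
# shared by the slower end-to-end tests.

toy_tracking <- function(n_frames = 12, rate = 30, n_players = 2,
                         possession = NULL) {
  frames <- 0:(n_frames - 1)
  mk_team <- function(team, x0) {
    do.call(rbind, lapply(seq_len(n_players) - 1L, function(p)
      data.frame(frame = frames, team = team, player = p,
                 x = x0 + p * 5 + frames * 0.1, y = 20 + p * 10)))
  }
  players <- rbind(mk_team("A", 30), mk_team("B", 60))
  ball <- data.frame(frame = frames, x = 40 + frames * 0.5, y = 34)
  if (is.null(possession))
    possession <- data.frame(frame = frames, team = "A")
  tracking_dataset(players, ball, possession, rate = rate,
                   rosters = list(A = 0:(n_players - 1),
                                  B = 0:(n_players - 1)))
}

.study_cache <- new.env(parent = emptyenv())

# The shared planted-signal study: simulated and featurized once per test
# run (it backs several independent checks).
shared_study <- function(n_bpis = 200, seed = 17, graph_rate = 5) {
  key <- paste(n_bpis, seed, graph_rate)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- simulate_study(
      sim_config(n_bpis = n_bpis, seed = seed), graph_rate = graph_rate)
  .study_cache[[key]]
}

# Planted-signal image set for fast model tests: class shifts one channel.
planted_images <- function(n_per_class = 40, shift = 1.5, Tlen = 25,
                           channel = 12, seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), each = n_per_class)
  x <- lapply(y, function(lab) {
    img <- array(stats::runif(11 * Tlen * 16), c(11, Tlen, 16))
    if (lab) img[, , channel] <- img[, , channel] + shift
    img
  })
  groups <- rep_len(1:20, length(y))
  ord <- sample(length(y))
  list(x = x[ord], y = y[ord], groups = groups[ord])
}
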