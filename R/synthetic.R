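#' Simulation configuration
#'
#' Parameters of the synthetic tracking-data generator. Players move by
#' Ornstein-Uhlenbeck (OU) dynamics around 4-4-2 formation anchors —
#' the simplest stationary, speed-bounded motion model with a tunable
#' spatial spread. The planted class signal lives in the defending team's
#' shape: in success intervals the defensive block is stretched along the
#' pitch and compressed across it, and one midfielder drifts out of his
#' zone, which thins the defending Delaunay graphs (lower degrees, longer
#' paths) and so shifts their walk entropy and eccentricity. The attacking
#' team behaves identically in both classes.
#'
#' @param pitch A [pitch_spec()].
#' @param rate Frame rate in Hz (default 30).
#' @param n_bpis Number of possession intervals to generate.
#' @param success_fraction Fraction of success-labeled intervals.
#' @param ou_theta OU mean-reversion rate, 1/s.
#' @param ou_sigma OU diffusion, m/sqrt(s).
#' @param max_speed Per-frame speed cap, m/s (default 8).
#' @param effect_size Planted defender displacement, metres: the defensive
#'   block is elongated by this much along x (and proportionally
#'   compressed in y), and the drifting defender's anchor moves by it.
#'   0 plants no signal (the classes become exchangeable).
#' @param duration_range Possession duration range in seconds; the minimum
#'   must be at least 10 s so the FETW and Target windows fit.
#' @param seed Integer seed; generation is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(pitch = pitch_spec(), rate = 30, n_bpis = 200,
                       success_fraction = 0.5, ou_theta = 0.5,
                       ou_sigma = 1.0, max_speed = 8, effect_size = 6,
                       duration_range = c(10, 15), seed = 1) {
  stopifnot(rate > 0, n_bpis >= 1, success_fraction > 0,
            success_fraction < 1, ou_theta > 0, ou_sigma > 0,
            max_speed > 0, effect_size >= 0,
            length(duration_range) == 2L, duration_range[1L] >= 10,
            duration_range[2L] >= duration_range[1L])
  structure(list(pitch = pitch, rate = rate, n_bpis = as.integer(n_bpis),
                 success_fraction = success_fraction, ou_theta = ou_theta,
                 ou_sigma = ou_sigma, max_speed = max_speed,
                 effect_size = effect_size, duration_range = duration_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Formation anchors on a pitch of the given size. The team in
## possession attacks +x in a 4-4-2 (rows = players 0..10: 0 goalkeeper,
## 1-4 backs, 5-8 midfield, 9-10 forwards). The defending baseline is a
## tight man-marking scheme: each outfield defender stands 0.8 m goal-
## side of his outfield counterpart, so marking contacts (opponent
## within 0.5 m) flicker continually under the motion noise.
formation_anchors <- function(pitch) {
  sx <- pitch$length / 105
  sy <- pitch$width / 68
  atk <- rbind(c(8, 34),
               cbind(28, c(12, 26, 42, 56)),
               cbind(48, c(12, 26, 42, 56)),
               cbind(66, c(26, 42)))
  def <- rbind(c(98, 34), atk[-1L, ] + cbind(rep(0.8, 10), 0))
  list(attacking = atk * cbind(rep(sx, 11), rep(sy, 11)),
       defending = def * cbind(rep(sx, 11), rep(sy, 11)))
}

## Planted tactical signal: the defence drops off its man-marking
## contact — every outfield defender retreats 0.2 * effect metres
## goal-side, the block dilates slightly, and one midfielder drifts
## from his zone. The retreat takes defenders out of marking range, so
## the marking-driven isolation that dominates the baseline class all
## but disappears; the shape itself changes only mildly.
spread_defenders <- function(anchors, effect, drifting, pitch) {
  if (effect <= 0) return(anchors)
  cx <- mean(anchors[-1L, 1L]); cy <- mean(anchors[-1L, 2L])
  span <- max(diff(range(anchors[-1L, 1L])),
              diff(range(anchors[-1L, 2L])))
  k <- 1 + 0.1 * effect / span
  a <- anchors
  a[-1L, 1L] <- cx + (a[-1L, 1L] - cx) * k + 0.2 * effect
  a[-1L, 2L] <- cy + (a[-1L, 2L] - cy) * k
  a[drifting + 1L, ] <- a[drifting + 1L, ] + 0.4 * c(effect, effect)
  if (any(a[, 1L] < 0 | a[, 1L] > pitch$length |
          a[, 2L] < 0 | a[, 2L] > pitch$width))
    stop("effect_size places defending anchors off the pitch")
  a
}

## OU trajectories around fixed anchors: matrix [frames x 2] per player.
ou_paths <- function(anchors, n, cfg) {
  dt <- 1 / cfg$rate
  max_step <- cfg$max_speed * dt
  npl <- nrow(anchors)
  sd0 <- cfg$ou_sigma / sqrt(2 * cfg$ou_theta)
  pos <- anchors + matrix(stats::rnorm(2 * npl, sd = sd0), npl, 2L)
  out <- array(0, c(n, npl, 2L))
  out[1L, , ] <- pos
  for (t in 2:n) {
    step <- cfg$ou_theta * (anchors - pos) * dt +
      cfg$ou_sigma * sqrt(dt) * matrix(stats::rnorm(2 * npl), npl, 2L)
    len <- sqrt(rowSums(step^2))
    too_fast <- len > max_step
    step[too_fast, ] <- step[too_fast, , drop = FALSE] *
      (max_step / len[too_fast])
    pos <- pos + step
    pos[, 1L] <- pmin(pmax(pos[, 1L], 0), cfg$pitch$length)
    pos[, 2L] <- pmin(pmax(pos[, 2L], 0), cfg$pitch$width)
    out[t, , ] <- pos
  }
  out
}

#' Simulate one possession interval
#'
#' Generates one ball-possession interval (at least 10 s) with the given
#' planted outcome: for `label = TRUE` (success) the defending team's
#' anchors carry the planted spread and the ball crosses the attacking-
#' zone boundary during the final 5 s; for failure the defence stays
#' compact and the ball never reaches the zone. The attacking team always
#' attacks towards `+x`.
#'
#' @param config A [sim_config()].
#' @param label Logical planted outcome.
#' @param seed Integer seed for this interval.
#' @param attacking_team `"A"` or `"B"`.
#' @return List with `players`, `ball` (local frames starting at 0),
#'   `n_frames`, `label`, `attacking_team`, `drifting_defender`.
#' @export
simulate_bpi <- function(config, label, seed = config$seed,
                         attacking_team = "A") {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  cfg <- config
  pitch <- cfg$pitch
  dur <- stats::runif(1, cfg$duration_range[1L], cfg$duration_range[2L])
  n <- as.integer(round(dur * cfg$rate))
  anchors <- formation_anchors(pitch)
  drifting <- sample(5:8, 1L)  # a midfielder leaves his zone
  def_anchors <- if (label)
    spread_defenders(anchors$defending, cfg$effect_size, drifting, pitch)
  else anchors$defending

  atk_path <- ou_paths(anchors$attacking, n, cfg)
  def_path <- ou_paths(def_anchors, n, cfg)

  ## Ball: smooth forward progress plus small noise; the crossing (or
  ## not) of the attacking-zone boundary is enforced by construction.
  thresh <- pitch$attack_fraction * pitch$length
  x0 <- stats::runif(1, 0.2, 0.42) * pitch$length
  xT <- if (label) stats::runif(1, thresh + 0.03 * pitch$length,
                                0.92 * pitch$length)
        else stats::runif(1, 0.45, 0.65) * pitch$length
  t_star <- n - as.integer(round(stats::runif(1, 0.5, 4) * cfg$rate))
  s <- pmin(seq_len(n) / max(t_star, 1L), 1)
  s <- s^2 * (3 - 2 * s)  # smoothstep
  bx <- x0 + (xT - x0) * s +
    stats::filter(stats::rnorm(n, sd = 0.3), 0.9, "recursive")
  by <- pitch$width / 2 +
    stats::filter(stats::rnorm(n, sd = 0.3), 0.95, "recursive")
  bx <- pmin(pmax(as.numeric(bx), 0), pitch$length)
  by <- pmin(pmax(as.numeric(by), 0), pitch$width)
  if (label) {
    bx[t_star] <- max(bx[t_star], thresh + 0.5)  # guarantee the crossing
  } else {
    bx <- pmin(bx, thresh - 0.5)  # never reach the zone
  }

  teams <- if (attacking_team == "A") c("A", "B") else c("B", "A")
  mk <- function(path, team) {
    data.frame(frame = rep(0:(n - 1L), each = 11L),
               time = rep(0:(n - 1L), each = 11L) / cfg$rate,
               team = team,
               player = rep(0:10, times = n),
               x = as.numeric(t(path[, , 1L])),
               y = as.numeric(t(path[, , 2L])))
  }
  list(players = rbind(mk(atk_path, teams[1L]), mk(def_path, teams[2L])),
       ball = data.frame(frame = 0:(n - 1L), x = bx, y = by),
       n_frames = n, label = label, attacking_team = teams[1L],
       drifting_defender = drifting)
}

#' Generate a full synthetic study dataset
#'
#' Simulates `n_bpis` possession intervals (possession alternating
#' between teams so interval boundaries are recoverable), concatenates
#' them into one tracking dataset, and assigns intervals round-robin to
#' 20 synthetic half-match groups, mirroring a 10-match evaluation
#' protocol. Class balance follows `success_fraction` exactly.
#'
#' @param config A [sim_config()].
#' @return List with `ds` (a [tracking_dataset()]), and `bpi_info`
#'   (data.frame `bpi_id`, `team`, `start_frame`, `end_frame`,
#'   `planted_label`, `group`).
#' @export
generate_dataset <- function(config) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  n <- config$n_bpis
  n_succ <- round(n * config$success_fraction)
  labels <- sample(c(rep(TRUE, n_succ), rep(FALSE, n - n_succ)))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  players <- vector("list", n); ball <- vector("list", n)
  info <- vector("list", n)
  offset <- 0L
  for (i in seq_len(n)) {
    team <- if (i %% 2L == 1L) "A" else "B"
    b <- simulate_bpi(config, labels[i], seed = seeds[i],
                      attacking_team = team)
    b$players$frame <- b$players$frame + offset
    b$players$time <- b$players$frame / config$rate
    b$ball$frame <- b$ball$frame + offset
    players[[i]] <- b$players
    ball[[i]] <- b$ball
    info[[i]] <- data.frame(bpi_id = i, team = team,
                            start_frame = offset,
                            end_frame = offset + b$n_frames,
                            planted_label = labels[i],
                            group = ((i - 1L) %% 20L) + 1L)
    offset <- offset + b$n_frames
  }
  info <- do.call(rbind, info)
  poss <- data.frame(
    frame = 0:(offset - 1L),
    team = rep(info$team, times = info$end_frame - info$start_frame))
  ds <- tracking_dataset(do.call(rbind, players), do.call(rbind, ball),
                         poss, rate = config$rate, pitch = config$pitch)
  list(ds = ds, bpi_info = info)
}

#' Simulate, segment, label and featurize a synthetic study
#'
#' End-to-end convenience: [generate_dataset()], [windowed_bpis()] (the
#' labels come from the pipeline's own Target-window test, not from the
#' planted flags), then raw rhythm tensors for every interval.
#'
#' @param config A [sim_config()].
#' @param graph_rate Graph sampling rate in Hz for the rhythm tensors
#'   (default 5; must divide `config$rate`).
#' @param params A [marking_params()].
#' @param metric_cfg A [metric_config()].
#' @return List with `images` (raw tensors), `labels` (pipeline labels),
#'   `groups`, `bpis` (the [windowed_bpis()] table) and `ds`.
#' @export
simulate_study <- function(config = sim_config(), graph_rate = 5,
                           params = marking_params(),
                           metric_cfg = metric_config()) {
  gen <- generate_dataset(config)
  bpis <- windowed_bpis(gen$ds)
  stopifnot(nrow(bpis) == nrow(gen$bpi_info))
  images <- build_rhythm_images(gen$ds, bpis, params, graph_rate,
                                metric_cfg)
  list(images = images, labels = bpis$label, groups = gen$bpi_info$group,
       bpis = bpis, ds = gen$ds)
}
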