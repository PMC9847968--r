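#' Pitch specification
#'
#' Defines the pitch geometry and the attacking-zone threshold used
#' throughout the pipeline. The coordinate convention is: origin at a pitch
#' corner, `x` in `[0, length]`, `y` in `[0, width]`, units metres, and the
#' attacking team always normalized (see
#' [normalize_attack_direction()]) to attack towards `+x`. The attacking
#' zone is the final quarter of the pitch, `x >= attack_fraction * length`.
#'
#' @param length Pitch length in metres (touchline-to-touchline along `x`).
#' @param width Pitch width in metres.
#' @param attack_fraction Fraction of `length` beyond which the attacking
#'   zone begins; the default 0.75 is the final quarter of the pitch.
#' @return An object of class `pitch_spec`.
#' @export
#' @examples
#' pitch_spec()
pitch_spec <- function(length = 105, width = 68, attack_fraction = 0.75) {
  stopifnot(is.numeric(length), length > 0,
            is.numeric(width), width > 0,
            is.numeric(attack_fraction),
            attack_fraction > 0, attack_fraction < 1)
  structure(list(length = length, width = width,
                 attack_fraction = attack_fraction),
            class = "pitch_spec")
}

#' @export
print.pitch_spec <- function(x, ...) {
  cat(sprintf("<pitch_spec> %g m x %g m, attacking zone x >= %g m\n",
              x$length, x$width, x$attack_fraction * x$length))
  invisible(x)
}

TEAM_IDS <- c("A", "B")

#' Assemble a tracking dataset
#'
#' Container for per-frame player and ball coordinates plus the per-frame
#' possession annotation. Frames are 0-indexed and `time = frame / rate`.
#' Players momentarily missing from a frame are carried forward from their
#' last known position for up to one second, then dropped from the frame.
#'
#' @param players data.frame with columns `frame`, `team` (`"A"`/`"B"`),
#'   `player` (roster index 0-10), `x`, `y` (metres). A `time` column is
#'   recomputed from `frame` and `rate`.
#' @param ball data.frame with columns `frame`, `x`, `y`.
#' @param possession data.frame with columns `frame`, `team`: the team in
#'   control of the ball at each frame.
#' @param rate Sampling rate in Hz.
#' @param pitch A [pitch_spec()].
#' @param rosters Named list mapping team id to its ordered player ids.
#' @return An object of class `tracking_dataset` with elements `rate`,
#'   `pitch`, `rosters`, `players`, `ball`, `possession`.
#' @export
tracking_dataset <- function(players, ball, possession, rate = 30,
                             pitch = pitch_spec(),
                             rosters = list(A = 0:10, B = 0:10)) {
  stopifnot(is.data.frame(players), is.data.frame(ball),
            is.data.frame(possession), rate > 0)
  need <- c("frame", "team", "player", "x", "y")
  miss <- setdiff(need, names(players))
  if (length(miss))
    stop("tracking table is missing required column(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(c("frame", "x", "y"), names(ball))
  if (length(miss))
    stop("ball table is missing required column(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(c("frame", "team"), names(possession))
  if (length(miss))
    stop("possession table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!all(players$team %in% TEAM_IDS))
    stop("player team ids must be one of: ", paste(TEAM_IDS, collapse = ", "))

  players <- players[order(players$frame, players$team, players$player), ,
                     drop = FALSE]
  ball <- ball[order(ball$frame), , drop = FALSE]
  possession <- possession[order(possession$frame), , drop = FALSE]
  if (anyDuplicated(possession$frame))
    stop("possession must define exactly one controlling team per frame")
  if (any(diff(possession$frame) != 1L))
    stop("non-monotone or gapped frame indices in possession table")

  ds <- structure(list(rate = rate, pitch = pitch, rosters = rosters,
                       players = players, ball = ball,
                       possession = possession),
                  class = "tracking_dataset")
  validate_tracking(ds)
}

#' @export
print.tracking_dataset <- function(x, ...) {
  cat(sprintf(
    "<tracking_dataset> %d frames @ %g Hz (%.1f s), %d player records\n",
    n_frames(x), x$rate, n_frames(x) / x$rate, nrow(x$players)))
  invisible(x)
}

#' Number of frames in a tracking dataset
#' @param ds A `tracking_dataset`.
#' @return Integer frame count.
#' @export
n_frames <- function(ds) {
  if (nrow(ds$possession) == 0L) return(0L)
  as.integer(max(ds$possession$frame) + 1L)
}

## Clip coordinates to the pitch, recompute time, fill short occlusion gaps.
validate_tracking <- function(ds) {
  p <- ds$pitch
  for (tab in c("players", "ball")) {
    d <- ds[[tab]]
    if (nrow(d) == 0L) next
    out <- d$x < 0 | d$x > p$length | d$y < 0 | d$y > p$width
    out[is.na(out)] <- FALSE
    if (any(out)) {
      message(sprintf("clipping %d out-of-pitch %s coordinate record(s)",
                      sum(out), sub("s$", "", tab)))
      d$x <- pmin(pmax(d$x, 0), p$length)
      d$y <- pmin(pmax(d$y, 0), p$width)
      ds[[tab]] <- d
    }
  }
  ds$players$time <- ds$players$frame / ds$rate
  ds$players <- fill_player_gaps(ds$players, ds$rate)
  rownames(ds$players) <- NULL
  rownames(ds$ball) <- NULL
  rownames(ds$possession) <- NULL
  ds
}

## Carry a player's last known position forward across gaps of <= 1 s.
fill_player_gaps <- function(players, rate) {
  if (nrow(players) == 0L) return(players)
  max_gap <- rate  # one second worth of frames
  key <- interaction(players$team, players$player, drop = TRUE)
  added <- list()
  for (k in levels(key)) {
    d <- players[key == k, , drop = FALSE]
    gaps <- diff(d$frame)
    idx <- which(gaps > 1L & gaps <= max_gap)
    for (i in idx) {
      fill <- (d$frame[i] + 1L):(d$frame[i + 1L] - 1L)
      added[[length(added) + 1L]] <- data.frame(
        frame = fill, time = fill / rate, team = d$team[i],
        player = d$player[i], x = d$x[i], y = d$y[i])
    }
  }
  if (length(added)) {
    players <- rbind(players, do.call(rbind, added))
    players <- players[order(players$frame, players$team, players$player), ,
                       drop = FALSE]
  }
  players
}

#' Read a tracking dataset from CSV
#'
#' Tracking CSV schema (long format, version 1): columns
#' `frame,time,team,player,x,y`, one row per player per frame, with the ball
#' given as sentinel team `"ball"` (its `player` column is ignored).
#' Lines starting with `#` are treated as comments, so files may carry a
#' versioned header comment. The possession CSV has columns `frame,team`.
#'
#' @param path Path to the tracking CSV.
#' @param possession_path Path to the possession CSV. Defaults to
#'   `<path without extension>_possession.csv`.
#' @param rate Sampling rate in Hz.
#' @param pitch A [pitch_spec()].
#' @return A [tracking_dataset()]. Out-of-pitch coordinates are clipped to
#'   the pitch with a message.
#' @seealso [write_tracking()]
#' @export
read_tracking <- function(path, possession_path = NULL, rate = 30,
                          pitch = pitch_spec()) {
  if (!file.exists(path)) stop("tracking file not found: ", path)
  if (is.null(possession_path))
    possession_path <- paste0(sub("\\.csv$", "", path), "_possession.csv")
  if (!file.exists(possession_path))
    stop("possession file not found: ", possession_path)
  raw <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("frame", "team", "player", "x", "y")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("tracking CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  poss <- utils::read.csv(possession_path, comment.char = "#",
                          stringsAsFactors = FALSE)
  is_ball <- raw$team == "ball"
  players <- raw[!is_ball, need, drop = FALSE]
  ball <- raw[is_ball, c("frame", "x", "y"), drop = FALSE]
  if (is.unsorted(unique(players$frame)))
    stop("non-monotone frame indices in tracking CSV")
  rosters <- lapply(split(players$player, players$team),
                    function(p) sort(unique(p)))
  tracking_dataset(players, ball, poss, rate = rate, pitch = pitch,
                   rosters = rosters)
}

#' Write a tracking dataset to CSV
#'
#' Inverse of [read_tracking()]: writes the long-format tracking CSV (ball
#' rows with sentinel team `"ball"`) with a versioned header comment, and
#' the possession CSV next to it.
#'
#' @param ds A `tracking_dataset`.
#' @param path Output tracking CSV path.
#' @param possession_path Output possession CSV path; same default rule as
#'   [read_tracking()].
#' @return `path`, invisibly.
#' @export
write_tracking <- function(ds, path, possession_path = NULL) {
  if (is.null(possession_path))
    possession_path <- paste0(sub("\\.csv$", "", path), "_possession.csv")
  ball <- ds$ball
  tab <- rbind(
    data.frame(frame = ds$players$frame, time = ds$players$time,
               team = ds$players$team, player = ds$players$player,
               x = ds$players$x, y = ds$players$y),
    if (nrow(ball)) data.frame(frame = ball$frame, time = ball$frame / ds$rate,
                               team = "ball", player = NA_integer_,
                               x = ball$x, y = ball$y))
  tab <- tab[order(tab$frame, tab$team, tab$player), , drop = FALSE]
  writeLines("# passrhythm tracking v1 (frame,time,team,player,x,y)", path)
  suppressWarnings(utils::write.table(
    tab, path, sep = ",", row.names = FALSE, quote = FALSE, append = TRUE))
  writeLines("# passrhythm possession v1 (frame,team)", possession_path)
  suppressWarnings(utils::write.table(
    ds$possession, possession_path, sep = ",", row.names = FALSE,
    quote = FALSE, append = TRUE))
  invisible(path)
}

#' Normalize the attacking direction of a team to +x
#'
#' Reflects all coordinates (`x -> length - x`, `y -> width - y`) if and
#' only if `team` attacks towards low `x`, so that downstream the attacking
#' zone is always the high-`x` quarter. The attack direction is either given
#' explicitly or inferred from the net ball displacement along `x` over the
#' frames in which `team` is in possession. Reflection is an isometry, so
#' all inter-player distances are preserved.
#'
#' @param ds A `tracking_dataset`.
#' @param team Team id whose attacking direction should become `+x`.
#' @param direction `"auto"` (infer from ball drift during possession),
#'   `"+x"` or `"-x"` (the team's current attacking direction).
#' @return The dataset, reflected if needed. Idempotent: applying it twice
#'   equals applying it once.
#' @export
normalize_attack_direction <- function(ds, team,
                                       direction = c("auto", "+x", "-x")) {
  direction <- match.arg(direction)
  if (!team %in% names(ds$rosters)) stop("unknown team: ", team)
  if (direction == "auto") {
    frames <- ds$possession$frame[ds$possession$team == team]
    b <- ds$ball[ds$ball$frame %in% frames, , drop = FALSE]
    drift <- if (nrow(b) >= 2L) sum(diff(b$x)) else 0
    direction <- if (drift < 0) "-x" else "+x"
  }
  if (direction == "+x") return(ds)
  p <- ds$pitch
  ds$players$x <- p$length - ds$players$x
  ds$players$y <- p$width - ds$players$y
  ds$ball$x <- p$length - ds$ball$x
  ds$ball$y <- p$width - ds$ball$y
  ds
}

#' Resample a tracking dataset to a lower rate
#'
#' Keeps every `rate / target_rate`-th frame (the target rate must divide
#' the current rate evenly) and renumbers frames consecutively from 0.
#' Possession labels follow the kept frames.
#'
#' @param ds A `tracking_dataset`.
#' @param target_rate New rate in Hz; must divide `ds$rate`.
#' @return A `tracking_dataset` at `target_rate`.
#' @export
resample_tracking <- function(ds, target_rate) {
  if (target_rate <= 0) stop("target_rate must be positive")
  step <- ds$rate / target_rate
  if (abs(step - round(step)) > 1e-9)
    stop(sprintf("target_rate %g does not divide the dataset rate %g",
                 target_rate, ds$rate))
  step <- as.integer(round(step))
  if (step == 1L) return(ds)
  keep <- function(frame) frame %% step == 0L
  renum <- function(frame) frame %/% step
  for (tab in c("players", "ball", "possession")) {
    d <- ds[[tab]][keep(ds[[tab]]$frame), , drop = FALSE]
    d$frame <- renum(d$frame)
    rownames(d) <- NULL
    ds[[tab]] <- d
  }
  ds$rate <- target_rate
  ds$players$time <- ds$players$frame / target_rate
  ds
}

## Positions of one team at one frame: named matrix (rows = player id).
team_positions <- function(ds, frame, team) {
  d <- ds$players[ds$players$frame == frame & ds$players$team == team, ,
                  drop = FALSE]
  m <- cbind(x = d$x, y = d$y)
  rownames(m) <- d$player
  m
}
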