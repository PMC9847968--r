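#' Marking filter parameters
#'
#' A player is "marked" when an opponent stands within `radius` metres
#' (inclusive). Marked players are treated as unable to give or receive a
#' pass, so every edge incident to them is suppressed in the pass graph.
#'
#' @param radius Marking radius in metres; the default 0.5 m follows the
#'   convention that an opponent 50 centimetres or closer marks a player.
#' @return An object of class `marking_params`.
#' @export
marking_params <- function(radius = 0.5) {
  stopifnot(is.numeric(radius), radius >= 0)
  structure(list(radius = radius), class = "marking_params")
}

#' Players marked by the opposing team
#'
#' @param team_positions Numeric matrix (x, y) of a team's players, row
#'   names = player ids.
#' @param opponent_positions Numeric matrix (x, y) of the opponents; may
#'   have zero rows.
#' @param params A [marking_params()].
#' @return Character vector of marked player ids (possibly empty): those
#'   whose minimum Euclidean distance to any opponent is `<= radius`.
#' @export
marked_players <- function(team_positions, opponent_positions,
                           params = marking_params()) {
  if (is.null(opponent_positions) || nrow(opponent_positions) == 0L)
    return(character())
  dx <- outer(team_positions[, 1L], opponent_positions[, 1L], "-")
  dy <- outer(team_positions[, 2L], opponent_positions[, 2L], "-")
  mind <- sqrt(apply(dx^2 + dy^2, 1L, min))
  rownames(team_positions)[mind <= params$radius]
}

#' Build one team's pass-possibility graph for a single frame
#'
#' Vertices are the team's tracked players; candidate edges are the
#' Delaunay edges of their positions (no teammate geometrically between
#' two Delaunay neighbours); the marking filter then removes every edge
#' incident to a marked player. Marked players remain as isolated vertices
#' so per-player metric rows stay aligned downstream.
#'
#' @param team_positions Matrix (x, y), row names = player ids, of the
#'   team whose graph is built.
#' @param opponent_positions Matrix (x, y) of the opposing team (used only
#'   for marking).
#' @param params A [marking_params()].
#' @param team,frame Optional identifiers stored on the result.
#' @return An object of class `pass_graph`: list with `team`, `frame`,
#'   `vertices` (player ids, in input row order), `edges` (two-column
#'   matrix of player ids), `positions`, `marked`.
#' @export
build_frame_graph <- function(team_positions, opponent_positions = NULL,
                              params = marking_params(),
                              team = NA_character_, frame = NA_integer_) {
  if (nrow(team_positions) < 1L)
    stop("team has no tracked players this frame")
  ids <- rownames(team_positions)
  if (is.null(ids)) {
    ids <- as.character(seq_len(nrow(team_positions)) - 1L)
    rownames(team_positions) <- ids
  }
  e <- delaunay_edges(team_positions)
  marked <- marked_players(team_positions, opponent_positions, params)
  if (length(marked) && nrow(e)) {
    midx <- match(marked, ids)
    e <- e[!(e[, 1L] %in% midx | e[, 2L] %in% midx), , drop = FALSE]
  }
  edges <- cbind(u = ids[e[, 1L]], v = ids[e[, 2L]])
  structure(list(team = team, frame = frame, vertices = ids,
                 edges = edges, positions = team_positions,
                 marked = marked),
            class = "pass_graph")
}

#' @export
print.pass_graph <- function(x, ...) {
  cat(sprintf("<pass_graph> team %s frame %s: %d vertices, %d edges, %d marked\n",
              x$team, x$frame, length(x$vertices), nrow(x$edges),
              length(x$marked)))
  invisible(x)
}

#' Adjacency matrix of a pass graph
#'
#' @param g A `pass_graph` (or a symmetric 0/1 matrix, returned as-is).
#' @param vertices Optional vertex ordering (player ids); defaults to the
#'   graph's own order. Ids absent from the graph appear as isolated rows.
#' @return Symmetric 0/1 numeric matrix with dimnames = vertex ids.
#' @export
pass_adjacency <- function(g, vertices = NULL) {
  if (is.matrix(g)) return(g)
  stopifnot(inherits(g, "pass_graph"))
  v <- if (is.null(vertices)) g$vertices else as.character(vertices)
  A <- matrix(0, length(v), length(v), dimnames = list(v, v))
  if (nrow(g$edges)) {
    iu <- match(g$edges[, 1L], v)
    iv <- match(g$edges[, 2L], v)
    ok <- !is.na(iu) & !is.na(iv)
    A[cbind(iu[ok], iv[ok])] <- 1
    A[cbind(iv[ok], iu[ok])] <- 1
  }
  A
}

#' Build the temporal pass-graph sequence over a window
#'
#' Samples the half-open frame window at `graph_rate` (which must divide
#' the dataset rate) and builds one [build_frame_graph()] per sampled frame.
#'
#' @param ds A `tracking_dataset`.
#' @param window Half-open frame range `c(start, end)` at the dataset rate.
#' @param team Team id whose graphs are built.
#' @param params A [marking_params()].
#' @param graph_rate Graph sampling rate in Hz (default: the dataset rate).
#' @return List of `pass_graph` objects, one per sampled frame; empty
#'   window gives an empty list.
#' @export
build_sequence <- function(ds, window, team, params = marking_params(),
                           graph_rate = ds$rate) {
  step <- ds$rate / graph_rate
  if (abs(step - round(step)) > 1e-9)
    stop("graph_rate must divide the dataset rate")
  step <- as.integer(round(step))
  if (window[2L] <= window[1L]) return(list())
  frames <- seq.int(window[1L], window[2L] - 1L, by = step)
  opp <- setdiff(names(ds$rosters), team)[1L]
  ## subset the window once; per-frame scans of the full table would make
  ## sequence building quadratic in match length
  sub <- ds$players[ds$players$frame %in% frames, , drop = FALSE]
  pos_of <- function(d) {
    m <- cbind(x = d$x, y = d$y)
    rownames(m) <- d$player
    m
  }
  own <- split(sub[sub$team == team, , drop = FALSE],
               factor(sub$frame[sub$team == team], levels = frames))
  other <- split(sub[sub$team == opp, , drop = FALSE],
                 factor(sub$frame[sub$team == opp], levels = frames))
  lapply(seq_along(frames), function(i)
    build_frame_graph(pos_of(own[[i]]), pos_of(other[[i]]),
                      params = params, team = team, frame = frames[i]))
}

#' Export per-frame edge lists to CSV
#'
#' @param graphs List of `pass_graph` objects.
#' @param path Output CSV path (columns `frame,team,u,v`).
#' @return `path`, invisibly.
#' @export
write_edge_lists <- function(graphs, path) {
  rows <- lapply(graphs, function(g) {
    if (nrow(g$edges) == 0L) return(NULL)
    data.frame(frame = g$frame, team = g$team,
               u = g$edges[, 1L], v = g$edges[, 2L])
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(frame = integer(), team = character(),
                      u = character(), v = character())
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
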