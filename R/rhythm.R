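#' Channel names of the 16-channel rhythm image
#'
#' Channels 1-8 hold the attacking team's eight metrics in the canonical
#' [rhythm_metrics()] order; channels 9-16 hold the defending team's, in
#' the same order.
#'
#' @return Character vector of length 16, e.g. `"attacking:betweenness"`.
#' @export
channel_names <- function() {
  c(paste0("attacking:", rhythm_metrics()),
    paste0("defending:", rhythm_metrics()))
}

#' Per-frame metric table for one team over a window
#'
#' Builds the pass-graph sequence for `team` over the half-open frame
#' `window` (sampled at `graph_rate`) and computes all eight per-vertex
#' metrics for every sampled frame.
#'
#' @inheritParams build_sequence
#' @param config A [metric_config()].
#' @return Tidy long data.frame: `col` (1-based column index in the
#'   window), `frame`, `team`, `player`, `metric`, `value`.
#' @export
compute_window_metrics <- function(ds, window, team,
                                   params = marking_params(),
                                   graph_rate = ds$rate,
                                   config = metric_config()) {
  graphs <- build_sequence(ds, window, team, params, graph_rate)
  rows <- lapply(seq_along(graphs), function(j) {
    m <- compute_all_metrics(graphs[[j]], config)
    vals <- as.matrix(m[, rhythm_metrics()])
    data.frame(col = j, frame = graphs[[j]]$frame, team = team,
               player = rep(m$player, times = length(rhythm_metrics())),
               metric = rep(rhythm_metrics(), each = nrow(m)),
               value = as.numeric(vals), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(col = integer(), frame = integer(), team = character(),
                      player = character(), metric = character(),
                      value = numeric())
  out
}

#' Build one visual-rhythm channel from a metric table
#'
#' Places the value of roster player i at sampled frame j into cell
#' `(i, j)` of an 11 x T matrix (rows follow roster order; roster slots
#' with no tracked player stay zero-filled).
#'
#' @param metric_table A [compute_window_metrics()] table for one team.
#' @param metric One of [rhythm_metrics()].
#' @param roster Ordered player ids defining the row mapping (default
#'   0-10).
#' @param T Number of columns; defaults to the largest `col` in the table.
#' @return Numeric matrix `length(roster) x T`, rownames = player ids.
#' @export
build_channel <- function(metric_table, metric, roster = 0:10, T = NULL) {
  if (!metric %in% rhythm_metrics())
    stop("unknown metric: ", metric)
  d <- metric_table[metric_table$metric == metric, , drop = FALSE]
  if (is.null(T)) T <- if (nrow(d)) max(d$col) else 0L
  F <- matrix(0, length(roster), T,
              dimnames = list(as.character(roster), NULL))
  if (nrow(d)) {
    ri <- match(as.character(d$player), as.character(roster))
    ok <- !is.na(ri) & d$col <= T
    if (any(!ok & !is.na(ri)))
      stop("metric table extends beyond the requested window")
    F[cbind(ri[ok], d$col[ok])] <- d$value[ok]
  }
  F
}

#' Raw (unnormalized) rhythm tensor of one possession interval
#'
#' Computes the 16-channel metric tensor of the FETW of one labeled
#' possession interval: channels 1-8 the possessing (attacking) team,
#' 9-16 the defending team, rows roster players, columns sampled frames.
#'
#' @param ds A `tracking_dataset`.
#' @param bpi One row of a [windowed_bpis()] table.
#' @param params A [marking_params()].
#' @param graph_rate Graph sampling rate in Hz (must divide the dataset
#'   rate).
#' @param config A [metric_config()].
#' @return Numeric array `11 x T x 16` with attributes `bpi_id`, `label`,
#'   `channel_order`.
#' @export
bpi_rhythm_raw <- function(ds, bpi, params = marking_params(),
                           graph_rate = ds$rate, config = metric_config()) {
  atk <- as.character(bpi$team)
  def <- setdiff(names(ds$rosters), atk)[1L]
  window <- c(bpi$fetw_start, bpi$fetw_end)
  mets <- rhythm_metrics()
  tabs <- list(attacking = compute_window_metrics(ds, window, atk, params,
                                                  graph_rate, config),
               defending = compute_window_metrics(ds, window, def, params,
                                                  graph_rate, config))
  Tlen <- max(1L, max(tabs$attacking$col, tabs$defending$col, 0L))
  roster_a <- ds$rosters[[atk]]
  roster_d <- ds$rosters[[def]]
  x <- array(0, dim = c(11L, Tlen, 16L),
             dimnames = list(NULL, NULL, channel_names()))
  for (k in seq_along(mets)) {
    x[, , k] <- pad_rows(build_channel(tabs$attacking, mets[k], roster_a,
                                       Tlen), 11L)
    x[, , 8L + k] <- pad_rows(build_channel(tabs$defending, mets[k],
                                            roster_d, Tlen), 11L)
  }
  attr(x, "bpi_id") <- bpi$bpi_id
  attr(x, "label") <- bpi$label
  attr(x, "channel_order") <- channel_names()
  x
}

pad_rows <- function(F, m) {
  if (nrow(F) == m) return(F)
  if (nrow(F) > m) stop("roster larger than ", m, " players")
  rbind(F, matrix(0, m - nrow(F), ncol(F)))
}

#' Raw rhythm tensors for every interval of a BPI table
#'
#' @inheritParams bpi_rhythm_raw
#' @param bpis A [windowed_bpis()] table.
#' @return List of raw `11 x T x 16` arrays (see [bpi_rhythm_raw()]), one
#'   per table row.
#' @export
build_rhythm_images <- function(ds, bpis, params = marking_params(),
                                graph_rate = ds$rate,
                                config = metric_config()) {
  lapply(seq_len(nrow(bpis)), function(i)
    bpi_rhythm_raw(ds, bpis[i, ], params, graph_rate, config))
}

#' Fit the per-channel min-max normalizer
#'
#' Records, for each of the 16 (metric, team-role) channels, the minimum
#' and maximum raw value over all supplied training tensors. Fit on
#' training data only and reused unchanged at test time, so no test
#' information leaks into the pixel scaling.
#'
#' @param images A raw rhythm tensor or list of them (see
#'   [bpi_rhythm_raw()]).
#' @return Object of class `rhythm_normalizer`: data.frame with `channel`,
#'   `name`, `min`, `max`.
#' @export
fit_normalizer <- function(images) {
  if (!is.list(images)) images <- list(images)
  stopifnot(length(images) >= 1L)
  lo <- rep(Inf, 16L); hi <- rep(-Inf, 16L)
  for (x in images) {
    stopifnot(length(dim(x)) == 3L, dim(x)[3L] == 16L)
    for (k in 1:16) {
      lo[k] <- min(lo[k], x[, , k])
      hi[k] <- max(hi[k], x[, , k])
    }
  }
  structure(data.frame(channel = 1:16, name = channel_names(),
                       min = lo, max = hi),
            class = c("rhythm_normalizer", "data.frame"))
}

#' Assemble a normalized 16-channel rhythm image
#'
#' Takes the 16 channels (named as in [channel_names()]) of one possession
#' interval, min-max scales each with the fitted normalizer, clips to
#' `[0, 1]`, and stacks them into the `11 x T x 16` image tensor. A
#' degenerate channel (`min == max` in training) maps to 0.
#'
#' @param channels Named list of 16 matrices `11 x T` (names =
#'   [channel_names()]), or a raw tensor from [bpi_rhythm_raw()].
#' @param normalizer A [fit_normalizer()] result.
#' @return Numeric array `11 x T x 16` with values in `[0, 1]`; `bpi_id`
#'   and `label` attributes are carried over when present.
#' @export
assemble_image <- function(channels, normalizer) {
  stopifnot(inherits(normalizer, "rhythm_normalizer"))
  if (is.array(channels) && length(dim(channels)) == 3L) {
    x <- channels
  } else {
    miss <- setdiff(channel_names(), names(channels))
    if (length(miss))
      stop("missing channel(s): ", paste(miss, collapse = ", "))
    Ts <- unique(vapply(channels, ncol, 1L))
    if (length(Ts) != 1L) stop("channels disagree on T")
    x <- array(0, dim = c(11L, Ts, 16L),
               dimnames = list(NULL, NULL, channel_names()))
    for (k in 1:16) x[, , k] <- pad_rows(channels[[channel_names()[k]]], 11L)
  }
  if (dim(x)[3L] != 16L) stop("exactly 16 channels are required")
  for (k in 1:16) {
    lo <- normalizer$min[k]; hi <- normalizer$max[k]
    x[, , k] <- if (hi > lo)
      pmin(pmax((x[, , k] - lo) / (hi - lo), 0), 1)
    else 0
  }
  x
}

#' Write one rhythm channel as a grayscale PNG
#'
#' Light pixels are high metric values. Requires the `png` package.
#'
#' @param channel An `11 x T` matrix with values in `[0, 1]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_channel_png <- function(channel, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  png::writePNG(pmin(pmax(channel, 0), 1), path)
  invisible(path)
}
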