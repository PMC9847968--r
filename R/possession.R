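#' Segment a match into ball-possession intervals
#'
#' A ball-possession interval (BPI) is a maximal run of consecutive frames
#' in which one team controls the ball. Intervals are half-open
#' `[start_frame, end_frame)`, non-overlapping, cover every annotated frame,
#' and change team at every boundary.
#'
#' @param ds A `tracking_dataset`.
#' @return data.frame with columns `bpi_id`, `team`, `start_frame`,
#'   `end_frame`, `duration` (seconds). Empty dataset gives zero rows.
#' @export
segment_bpis <- function(ds) {
  poss <- ds$possession
  if (nrow(poss) == 0L)
    return(data.frame(bpi_id = integer(), team = character(),
                      start_frame = integer(), end_frame = integer(),
                      duration = numeric()))
  r <- rle(as.character(poss$team))
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  first <- poss$frame[1L]
  data.frame(bpi_id = seq_along(r$values),
             team = r$values,
             start_frame = first + starts,
             end_frame = first + ends,
             duration = r$lengths / ds$rate)
}

#' Split a possession interval into FETW / Lag / Target windows
#'
#' The feature-extraction time window (FETW) is the first `fetw_seconds` of
#' the interval and is the only part the classifier ever sees; the Target is
#' the last `target_seconds` and is used solely for labeling; the Lag is
#' whatever remains in the middle (possibly empty). Intervals shorter than
#' `fetw_seconds + target_seconds` cannot be split and raise a condition of
#' class `"bpi_discard"`; callers drop such intervals (see
#' [windowed_bpis()]).
#'
#' @param bpi One row of the [segment_bpis()] table (or any list with
#'   `start_frame`, `end_frame`).
#' @param rate Frame rate in Hz of the dataset the frames refer to.
#' @param fetw_seconds FETW length in seconds (default 5).
#' @param target_seconds Target length in seconds (default 5).
#' @return List with half-open frame ranges `fetw`, `lag`, `target`, each
#'   `c(start, end)`; the three partition `[start_frame, end_frame)`.
#' @export
split_windows <- function(bpi, rate, fetw_seconds = 5, target_seconds = 5) {
  nf <- as.integer(round(fetw_seconds * rate))
  nt <- as.integer(round(target_seconds * rate))
  len <- bpi$end_frame - bpi$start_frame
  if (len < nf + nt) {
    cond <- structure(
      class = c("bpi_discard", "error", "condition"),
      list(message = sprintf(
             "possession interval of %d frame(s) is shorter than fetw+target (%d)",
             len, nf + nt),
           call = sys.call(-1)))
    stop(cond)
  }
  list(fetw = c(bpi$start_frame, bpi$start_frame + nf),
       lag = c(bpi$start_frame + nf, bpi$end_frame - nt),
       target = c(bpi$end_frame - nt, bpi$end_frame))
}

#' Label a possession interval as success or failure
#'
#' Success means the ball reached the attacking zone (the final quarter of
#' the pitch, `x >= attack_fraction * length`, inclusive) during at least
#' one frame of the Target window. Only the Target window is assessed: a
#' crossing during the Lag that retreats before the Target does not count.
#' The dataset must already be normalized so the interval's team attacks
#' towards `+x` (see [normalize_attack_direction()]).
#'
#' @param ds A `tracking_dataset`, attack direction normalized.
#' @param split A [split_windows()] result.
#' @param pitch A [pitch_spec()]; defaults to the dataset's.
#' @return Logical: `TRUE` for success.
#' @export
label_bpi <- function(ds, split, pitch = ds$pitch) {
  frames <- split$target[1L]:(split$target[2L] - 1L)
  b <- ds$ball[ds$ball$frame %in% frames, , drop = FALSE]
  if (nrow(b) == 0L)
    stop("ball track missing in the Target window")
  any(b$x >= pitch$attack_fraction * pitch$length)
}

#' Segment, window and label every possession interval of a match
#'
#' Convenience driver: runs [segment_bpis()], drops intervals shorter than
#' `fetw_seconds + target_seconds` (with a message reporting how many), and
#' labels the kept ones via [label_bpi()] after per-interval attack-direction
#' normalization.
#'
#' @inheritParams split_windows
#' @param ds A `tracking_dataset`.
#' @return data.frame with columns `bpi_id`, `team`, `start_frame`,
#'   `end_frame`, `duration`, the six window boundary columns
#'   (`fetw_start`, `fetw_end`, `lag_start`, `lag_end`, `target_start`,
#'   `target_end`) and logical `label`.
#' @export
windowed_bpis <- function(ds, fetw_seconds = 5, target_seconds = 5) {
  bpis <- segment_bpis(ds)
  out <- vector("list", nrow(bpis))
  dropped <- 0L
  for (i in seq_len(nrow(bpis))) {
    bpi <- bpis[i, ]
    split <- tryCatch(
      split_windows(bpi, ds$rate, fetw_seconds, target_seconds),
      bpi_discard = function(e) NULL)
    if (is.null(split)) { dropped <- dropped + 1L; next }
    dsn <- normalize_attack_direction(ds, bpi$team)
    out[[i]] <- cbind(bpi,
                      fetw_start = split$fetw[1L], fetw_end = split$fetw[2L],
                      lag_start = split$lag[1L], lag_end = split$lag[2L],
                      target_start = split$target[1L],
                      target_end = split$target[2L],
                      label = label_bpi(dsn, split))
  }
  if (dropped > 0L)
    message(sprintf("dropped %d possession interval(s) shorter than %g s",
                    dropped, fetw_seconds + target_seconds))
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- cbind(bpis[0, ], fetw_start = integer(), fetw_end = integer(),
                 lag_start = integer(), lag_end = integer(),
                 target_start = integer(), target_end = integer(),
                 label = logical())
  rownames(out) <- NULL
  out
}

#' Write a labeled BPI table to CSV
#'
#' @param bpis A [windowed_bpis()] table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bpi_table <- function(bpis, path) {
  utils::write.csv(bpis, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
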