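#' Score sleep from per-minute activity counts
#'
#' Applies the standard fly-sleep convention: any maximal run of zero-count
#' minutes of length `min_bout_minutes` (default 5) or more is sleep, in its
#' entirety, including the first four minutes; shorter zero runs are wake.
#' Runs touching the recording edges count if long enough.
#'
#' @param table an activity table (see [read_dam()]); the minute grid must be
#'   gapless per fly.
#' @param min_bout_minutes minimum inactive run length scored as sleep.
#' @return A `data.table` sleep series with columns `fly_id`, `t`, `zt`,
#'   `asleep`, on the same grid as `table`.
#' @export
score_sleep <- function(table, min_bout_minutes = 5L) {
  dt <- check_activity_table(table)
  if (min_bout_minutes < 1L)
    stop("min_bout_minutes must be >= 1", call. = FALSE)
  if (any(dt$count < 0))
    stop("counts must be non-negative", call. = FALSE)
  data.table::setkey(dt, fly_id, t)
  out <- dt[, {
    r <- rle(count == 0L)
    list(t = t, zt = zt,
         asleep = rep(r$values & r$lengths >= min_bout_minutes, r$lengths))
  }, by = fly_id]
  data.table::setkey(out, fly_id, t)
  out[]
}

#' Extract maximal sleep bouts from a sleep series
#'
#' @param series a sleep series from [score_sleep()].
#' @return A `data.table` with columns `fly_id`, `start_t`, `duration`
#'   (minutes), sorted and disjoint; the union of bouts is exactly the set
#'   of asleep minutes.
#' @export
sleep_bouts <- function(series) {
  dt <- check_sleep_series(series)
  data.table::setkey(dt, fly_id, t)
  out <- dt[, {
    r <- rle(asleep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i <- which(r$values)
    list(start_t = t[starts[i]], duration = r$lengths[i])
  }, by = fly_id]
  data.table::setkey(out, fly_id, start_t)
  out[]
}

#' Total sleep within a half-open minute window
#'
#' Bouts straddling a window boundary contribute only their in-window
#' minutes.
#'
#' @param series a sleep series.
#' @param window integer `c(start_t, end_t)`, half-open `[start, end)`.
#' @return A `data.table` with columns `fly_id` and `sleep_min`.
#' @export
sleep_in_window <- function(series, window) {
  dt <- check_sleep_series(series)
  check_window(dt, window)
  if (window[2] == window[1])
    return(dt[, .(sleep_min = 0L), by = fly_id])
  out <- dt[t >= window[1] & t < window[2],
            .(sleep_min = sum(asleep)), by = fly_id]
  data.table::setkey(out, fly_id)
  out[]
}

#' Latency to sleep within a window
#'
#' Latency is measured from the window start to the onset of the first sleep
#' bout whose onset lies in the window; a bout already in progress at the
#' window start counts as onset at the window start (latency 0). When no
#' onset occurs in-window the latency equals the window length and is
#' flagged as censored rather than dropped.
#'
#' @param series a sleep series.
#' @param window integer `c(start_t, end_t)`, half-open.
#' @return A `data.table` with columns `fly_id`, `latency` (minutes) and
#'   `censored`.
#' @export
sleep_latency <- function(series, window) {
  dt <- check_sleep_series(series)
  check_window(dt, window)
  len <- window[2] - window[1]
  out <- dt[t >= window[1] & t < window[2], {
    i <- which(asleep)[1]
    if (is.na(i)) list(latency = as.integer(len), censored = TRUE)
    else list(latency = t[i] - window[1], censored = FALSE)
  }, by = fly_id]
  data.table::setkey(out, fly_id)
  out[]
}

#' Export a scored trace as CSV
#'
#' Writes the merged per-minute table (`fly_id`, `t`, `zt`, `count`,
#' `asleep`) used by downstream tools.
#'
#' @param series a sleep series.
#' @param table the activity table it was scored from.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_sleep_csv <- function(series, table, path) {
  dt <- check_activity_table(table)
  ss <- check_sleep_series(series)
  merged <- merge(dt, ss[, .(fly_id, t, asleep)], by = c("fly_id", "t"))
  data.table::fwrite(merged[order(fly_id, t)], path)
  invisible(path)
}

check_window <- function(dt, window) {
  if (length(window) != 2L || window[2] < window[1])
    stop("window must be c(start_t, end_t) with end >= start", call. = FALSE)
  if (window[1] < min(dt$t) || window[2] > max(dt$t) + 1L)
    stop("range error: window [", window[1], ", ", window[2],
         ") outside series extent", call. = FALSE)
  invisible(window)
}
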