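#' Build the full ultradian scheduled-sleep-deprivation protocol
#'
#' The full SSD protocol applies a 2.5 h mechanical deprivation followed by a
#' 4.5 h rebound opportunity on a 7 h cycle. Because gcd(7, 24) = 1, running
#' 24 consecutive episodes places one rebound onset in every one-hour residue
#' class of the 24 h day, so homeostatic rebound can be probed at each clock
#' hour.
#'
#' @param first_onset_zt zeitgeber time (hours) at which the first rebound
#'   begins; episode `k` then has onset `(first_onset_zt + 7 k) mod 24`.
#' @param n_episodes number of deprivation episodes (24 for full coverage).
#' @param zt0_minute minute index of ZT0 on the first deprivation day; the
#'   two full days immediately before it are the baseline days, so it must
#'   be at least 2880.
#' @return An `ssd_schedule` object: a list with `episodes` (a `data.table`
#'   with `index`, `sd_start_t`, `sd_end_t`, `rebound_end_t`, `onset_zt`),
#'   `baseline_day_starts`, `zt0_minute` and `mode`.
#' @export
make_full_ssd <- function(first_onset_zt = 4.5, n_episodes = 24L,
                          zt0_minute = 2880L) {
  if (n_episodes < 1L) stop("n_episodes must be >= 1", call. = FALSE)
  if (first_onset_zt < 0 || first_onset_zt >= 24)
    stop("first_onset_zt must lie in [0, 24)", call. = FALSE)
  if (zt0_minute < 2 * MIN_PER_DAY)
    stop("zt0_minute must leave room for 2 full baseline days", call. = FALSE)
  start_offset <- round(((first_onset_zt - 2.5) * 60)) %% MIN_PER_DAY
  sd_start <- as.integer(zt0_minute + start_offset +
                           EPISODE_MINUTES * (seq_len(n_episodes) - 1L))
  new_schedule(sd_start, zt0_minute, mode = "full")
}

#' Build the abridged scheduled-sleep-deprivation protocol
#'
#' The streamlined protocol applies the 2.5 h stimulus five times: at ZT0,
#' ZT8 and ZT23 of the first deprivation day, ZT7 of the next day and ZT6 of
#' the day after, yielding rebound onsets at ZT2.5, 10.5, 1.5, 9.5 and 8.5 -
#' two morning and three evening probes.
#'
#' @inheritParams make_full_ssd
#' @return An `ssd_schedule` object (see [make_full_ssd()]).
#' @export
make_abridged_ssd <- function(zt0_minute = 2880L) {
  if (zt0_minute < 2 * MIN_PER_DAY)
    stop("zt0_minute must leave room for 2 full baseline days", call. = FALSE)
  day <- c(0L, 0L, 0L, 1L, 2L)
  sd_zt <- c(0L, 8L, 23L, 7L, 6L)
  sd_start <- as.integer(zt0_minute + day * MIN_PER_DAY + sd_zt * 60L)
  new_schedule(sort(sd_start), zt0_minute, mode = "abridged")
}

new_schedule <- function(sd_start, zt0_minute, mode) {
  episodes <- data.table::data.table(
    index = seq_along(sd_start) - 1L,
    sd_start_t = sd_start,
    sd_end_t = sd_start + SD_MINUTES,
    rebound_end_t = sd_start + EPISODE_MINUTES
  )
  episodes[, onset_zt := ((sd_end_t - zt0_minute) %% MIN_PER_DAY) / 60]
  structure(
    list(episodes = episodes[],
         baseline_day_starts = as.integer(zt0_minute - c(2L, 1L) * MIN_PER_DAY),
         zt0_minute = as.integer(zt0_minute),
         mode = mode),
    class = "ssd_schedule")
}

#' @export
print.ssd_schedule <- function(x, ...) {
  cat(sprintf("SSD schedule (%s): %d episodes, baseline days at t = %s\n",
              x$mode, nrow(x$episodes),
              paste(x$baseline_day_starts, collapse = ", ")))
  print(x$episodes)
  invisible(x)
}

#' Number of recording days needed to cover a schedule
#' @param schedule an `ssd_schedule`.
#' @return integer number of whole days.
#' @export
schedule_days <- function(schedule) {
  as.integer(ceiling(max(schedule$episodes$rebound_end_t) / MIN_PER_DAY))
}

#' Validate a deprivation schedule
#'
#' Checks episode durations (2.5 h SD, 4.5 h rebound), episode overlap,
#' coverage by the recording (when an activity table is supplied) and, for
#' full-mode schedules, that the 24 rebound onsets cover all 24 one-hour
#' residue classes.
#'
#' @param schedule an `ssd_schedule`.
#' @param table optional activity table the schedule will be analyzed on.
#' @return A `data.table` of violations (`type`, `message`); zero rows when
#'   the schedule is compliant.
#' @export
validate_schedule <- function(schedule, table = NULL) {
  ep <- schedule$episodes
  v <- list()
  bad_sd <- ep[sd_end_t - sd_start_t != SD_MINUTES]
  if (nrow(bad_sd))
    v <- c(v, list(data.table::data.table(
      type = "duration",
      message = sprintf("episode %d: SD window is not %d min",
                        bad_sd$index, SD_MINUTES))))
  bad_rb <- ep[rebound_end_t - sd_end_t != REBOUND_MINUTES]
  if (nrow(bad_rb))
    v <- c(v, list(data.table::data.table(
      type = "duration",
      message = sprintf("episode %d: rebound window is not %d min",
                        bad_rb$index, REBOUND_MINUTES))))
  if (nrow(ep) > 1L) {
    s <- ep[order(sd_start_t)]
    ov <- which(s$sd_start_t[-1L] < s$rebound_end_t[-nrow(s)])
    if (length(ov))
      v <- c(v, list(data.table::data.table(
        type = "overlap",
        message = sprintf("episodes %d and %d overlap",
                          s$index[ov], s$index[ov + 1L]))))
  }
  if (identical(schedule$mode, "full")) {
    classes <- unique(floor(ep$onset_zt) %% 24)
    if (length(classes) < 24L)
      v <- c(v, list(data.table::data.table(
        type = "residue_coverage",
        message = sprintf("rebound onsets cover %d of 24 one-hour residue classes",
                          length(classes)))))
  }
  if (!is.null(table)) {
    dt <- check_activity_table(table, require_gapless = FALSE)
    if (min(schedule$baseline_day_starts) < min(dt$t) ||
        max(ep$rebound_end_t) > max(dt$t) + 1L)
      v <- c(v, list(data.table::data.table(
        type = "range",
        message = "schedule extends beyond the recording extent")))
  }
  if (length(v)) data.table::rbindlist(v) else
    data.table::data.table(type = character(0), message = character(0))
}

#' Stimulus onset times within a deprivation episode
#'
#' The mechanical protocol applies a 2 s vibration approximately every 20 s
#' with randomized jitter. Onsets are generated at second resolution within
#' `[sd_start, sd_end)`; inter-onset intervals are drawn uniformly from
#' `interval_s` plus or minus `jitter_s`. Used by the simulator only - the
#' cohort generator abstracts the train as a per-minute wake-forcing
#' probability.
#'
#' @param episode one row of `schedule$episodes` (or an equivalent list).
#' @param interval_s nominal inter-stimulus interval in seconds.
#' @param jitter_s half-width of the uniform jitter band in seconds.
#' @param seed optional RNG seed for reproducible trains.
#' @return Numeric vector of onset times in seconds from recording start.
#' @export
stimulus_times <- function(episode, interval_s = 20, jitter_s = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start_s <- episode$sd_start_t * 60
  end_s <- episode$sd_end_t * 60
  n_max <- ceiling((end_s - start_s) / max(interval_s - jitter_s, 1)) + 1L
  gaps <- if (jitter_s > 0)
    stats::runif(n_max, interval_s - jitter_s, interval_s + jitter_s)
  else rep(interval_s, n_max)
  onsets <- start_s + c(0, cumsum(gaps))
  onsets[onsets < end_s]
}

#' Export a schedule to JSON
#' @param schedule an `ssd_schedule`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
schedule_to_json <- function(schedule, path) {
  jsonlite::write_json(
    list(mode = schedule$mode,
         zt0_minute = schedule$zt0_minute,
         baseline_day_starts = schedule$baseline_day_starts,
         episodes = schedule$episodes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a schedule from JSON
#' @param path a file written by [schedule_to_json()].
#' @return An `ssd_schedule`.
#' @export
schedule_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ep <- data.table::as.data.table(x$episodes)
  int_cols <- c("index", "sd_start_t", "sd_end_t", "rebound_end_t")
  ep[, (int_cols) := lapply(.SD, as.integer), .SDcols = int_cols]
  structure(
    list(episodes = ep[],
         baseline_day_starts = as.integer(x$baseline_day_starts),
         zt0_minute = as.integer(x$zt0_minute),
         mode = x$mode),
    class = "ssd_schedule")
}
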