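#' Averaged daily activity eduction
#'
#' Folds activity onto a 24 h clock axis: for each clock bin, the mean over
#' flies and requested days of the total beam crossings in that bin.
#'
#' @param table an activity table (recording assumed to start at ZT0 if `zt`
#'   is derived that way; bins are placed on `zt`).
#' @param days integer day indices (1-based: day `d` spans minutes
#'   `[(d-1)*1440, d*1440)`).
#' @param bin_minutes clock bin width; must divide 1440.
#' @return A `daily_profile` object: a list with `values` (a `data.table`
#'   of `bin_start_zt`, `value`), `bin_minutes`, `n_days`, `n_flies` and
#'   `kind = "activity"`.
#' @export
eduction <- function(table, days, bin_minutes = 30L) {
  dt <- check_activity_table(table)
  check_bin(bin_minutes)
  day_span <- range(dt$t)
  need <- (max(days) * MIN_PER_DAY) - 1L
  if (min(days) < 1L || need > day_span[2])
    stop("range error: requested days absent from the table", call. = FALSE)
  sub <- dt[t %/% MIN_PER_DAY %in% (days - 1L)]
  sub[, bin := floor(round(zt * 60) / bin_minutes)]
  per <- sub[, .(s = sum(count)), by = .(fly_id, day = t %/% MIN_PER_DAY, bin)]
  vals <- per[, .(value = mean(s)), by = bin][order(bin)]
  new_daily_profile(vals, bin_minutes, n_days = length(days),
                    n_flies = length(unique(dt$fly_id)), kind = "activity")
}

#' Baseline sleep profile
#'
#' Mean sleep minutes per clock bin over the baseline days, plus the total
#' daily sleep (the sum over bins).
#'
#' @param series a sleep series from [score_sleep()].
#' @param baseline_day_starts minute indices of baseline day starts (each at
#'   ZT0), e.g. `schedule$baseline_day_starts`.
#' @param bin_minutes clock bin width; must divide 1440.
#' @return A `daily_profile` (kind `"sleep"`) with attribute
#'   `total_daily_sleep` = sum of bin values.
#' @export
baseline_sleep_profile <- function(series, baseline_day_starts,
                                   bin_minutes = 30L) {
  dt <- check_sleep_series(series)
  check_bin(bin_minutes)
  if (min(baseline_day_starts) < min(dt$t) ||
      max(baseline_day_starts) + MIN_PER_DAY > max(dt$t) + 1L)
    stop("range error: baseline days absent from the series", call. = FALSE)
  parts <- lapply(baseline_day_starts, function(b)
    dt[t >= b & t < b + MIN_PER_DAY,
       .(fly_id, off = t - b, asleep, day_start = b)])
  sub <- data.table::rbindlist(parts)
  sub[, bin := off %/% bin_minutes]
  per <- sub[, .(s = sum(asleep)), by = .(fly_id, day_start, bin)]
  vals <- per[, .(value = mean(s)), by = bin][order(bin)]
  p <- new_daily_profile(vals, bin_minutes,
                         n_days = length(baseline_day_starts),
                         n_flies = length(unique(dt$fly_id)), kind = "sleep")
  attr(p, "total_daily_sleep") <- sum(p$values$value)
  p
}

#' Anticipation index at a light transition
#'
#' Quantifies clock-driven anticipation as a normalized contrast of activity
#' approaching a light transition:
#' `AI = (A_near - A_far) / (A_near + A_far)`, where `A_near` sums activity
#' in the `window_hours` immediately preceding the transition and `A_far`
#' the `window_hours` before that. Bounded in `[-1, 1]`, zero when activity
#' is flat, positive when activity ramps up toward the transition, and
#' invariant to uniform rescaling of counts. The lights-off transition uses
#' the same formula mirrored at ZT12. Undefined (NA, flagged) when both
#' sums are zero.
#'
#' @param profile a `daily_profile` from [eduction()].
#' @param transition `"lights_on"` (transition at ZT24/0) or `"lights_off"`
#'   (ZT12).
#' @param window_hours width of each contrast window (default 3 h).
#' @return A list with `transition`, `value`, `a_near`, `a_far` and
#'   `defined`.
#' @export
anticipation_index <- function(profile, transition = c("lights_on", "lights_off"),
                               window_hours = 3) {
  transition <- match.arg(transition)
  tz <- if (transition == "lights_on") 24 else 12
  if (tz - 2 * window_hours < 0)
    stop("range error: profile cannot cover 2 anticipation windows", call. = FALSE)
  starts <- profile$values$bin * profile$bin_minutes / 60
  near <- starts >= tz - window_hours & starts < tz
  far <- starts >= tz - 2 * window_hours & starts < tz - window_hours
  a_near <- sum(profile$values$value[near])
  a_far <- sum(profile$values$value[far])
  if (a_near + a_far == 0)
    return(list(transition = transition, value = NA_real_,
                a_near = a_near, a_far = a_far, defined = FALSE))
  list(transition = transition,
       value = (a_near - a_far) / (a_near + a_far),
       a_near = a_near, a_far = a_far, defined = TRUE)
}

new_daily_profile <- function(vals, bin_minutes, n_days, n_flies, kind) {
  full <- data.table::data.table(bin = 0:(MIN_PER_DAY / bin_minutes - 1L))
  vals <- merge(full, vals, by = "bin", all.x = TRUE)
  vals[is.na(value), value := 0]
  vals[, bin_start_zt := bin * bin_minutes / 60]
  structure(
    list(values = vals[, .(bin, bin_start_zt, value)],
         bin_minutes = as.integer(bin_minutes),
         n_days = n_days, n_flies = n_flies, kind = kind),
    class = "daily_profile")
}

#' @export
print.daily_profile <- function(x, ...) {
  cat(sprintf("daily %s profile: %d bins of %d min, %d flies x %d days\n",
              x$kind, nrow(x$values), x$bin_minutes, x$n_flies, x$n_days))
  invisible(x)
}

check_bin <- function(bin_minutes) {
  if (bin_minutes < 1L || MIN_PER_DAY %% bin_minutes != 0L)
    stop("bin_minutes must divide 1440", call. = FALSE)
  invisible(bin_minutes)
}
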