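#' Per-fly, per-episode homeostasis metrics
#'
#' For each fly and each deprivation episode computes:
#' \describe{
#'   \item{sleep lost}{baseline sleep in the SD clock window minus sleep
#'     obtained during the SD window;}
#'   \item{sleep gain}{sleep during the 4.5 h rebound window minus baseline
#'     sleep in the equivalent clock window;}
#'   \item{deprivation efficiency}{sleep lost divided by baseline SD-window
#'     sleep (undefined when the baseline is zero);}
#'   \item{latency}{minutes from the end of deprivation to the first sleep
#'     bout onset, censored at the window length.}
#' }
#' Baseline references are the mean, over the two full baseline days, of
#' sleep in the matching clock window; clock windows are evaluated
#' circularly within each baseline day, so windows wrapping past midnight
#' never leak outside the baseline period.
#'
#' @param series a sleep series from [score_sleep()] covering the baseline
#'   days and all requested episodes for every fly.
#' @param schedule an `ssd_schedule`.
#' @param episodes optional integer episode indices (0-based); default all.
#' @return A `data.table` with one row per fly and episode: `fly_id`,
#'   `episode_index`, `onset_zt`, `baseline_sleep_sd_window`, `sd_sleep`,
#'   `sleep_lost`, `baseline_sleep_rebound_window`, `rebound_sleep`,
#'   `sleep_gain`, `efficiency`, `latency`, `latency_censored`.
#' @export
episode_metrics <- function(series, schedule, episodes = NULL) {
  A <- sleep_matrix(series)
  t0 <- attr(A, "t0")
  flies <- colnames(A)
  ep <- schedule$episodes
  if (!is.null(episodes)) {
    ep <- ep[index %in% episodes]
    if (!nrow(ep)) stop("no matching episodes", call. = FALSE)
  }
  if (min(schedule$baseline_day_starts) < t0 ||
      max(ep$rebound_end_t) > t0 + nrow(A))
    stop("range error: series does not cover baseline days and episodes",
         call. = FALSE)

  # minute-of-day sleep, one column per fly per baseline day
  bl <- lapply(schedule$baseline_day_starts, function(b) {
    A[(b - t0 + 1L):(b - t0 + MIN_PER_DAY), , drop = FALSE]
  })
  zt0 <- schedule$zt0_minute

  rows <- lapply(seq_len(nrow(ep)), function(i) {
    e <- ep[i]
    sd_idx <- (e$sd_start_t - t0 + 1L):(e$sd_end_t - t0)
    rb_idx <- (e$sd_end_t - t0 + 1L):(e$rebound_end_t - t0)
    off_sd <- ((e$sd_start_t - zt0) + 0:(SD_MINUTES - 1L)) %% MIN_PER_DAY + 1L
    off_rb <- ((e$sd_end_t - zt0) + 0:(REBOUND_MINUTES - 1L)) %% MIN_PER_DAY + 1L
    day_sums <- function(off) {
      s <- vapply(bl, function(m) colSums(m[off, , drop = FALSE]),
                  numeric(length(flies)))
      rowMeans(matrix(s, nrow = length(flies)))
    }
    base_sd <- day_sums(off_sd)
    base_rb <- day_sums(off_rb)
    sd_sleep <- colSums(A[sd_idx, , drop = FALSE])
    rb_sleep <- colSums(A[rb_idx, , drop = FALSE])
    lat <- apply(A[rb_idx, , drop = FALSE], 2L, function(z) which(z)[1])
    censored <- is.na(lat)
    lat[censored] <- length(rb_idx) + 1L
    data.table::data.table(
      fly_id = flies,
      episode_index = e$index,
      onset_zt = e$onset_zt,
      baseline_sleep_sd_window = base_sd,
      sd_sleep = sd_sleep,
      sleep_lost = base_sd - sd_sleep,
      baseline_sleep_rebound_window = base_rb,
      rebound_sleep = rb_sleep,
      sleep_gain = rb_sleep - base_rb,
      efficiency = ifelse(base_sd > 0, (base_sd - sd_sleep) / base_sd, NA_real_),
      latency = as.integer(lat - 1L),
      latency_censored = censored)
  })
  out <- data.table::rbindlist(rows)
  data.table::setkey(out, fly_id, episode_index)
  out[]
}

#' Apply the deprivation-efficiency inclusion filter
#'
#' A fly (default scope) is retained only if its deprivation efficiency
#' exceeds `threshold` at every episode with nonzero baseline SD-window
#' sleep; episodes where no baseline sleep fell in the SD window impose no
#' constraint (one cannot deprive sleep that would not have occurred).
#' With `scope = "episode"` individual fly-by-episode records are filtered
#' instead.
#'
#' @param metrics output of [episode_metrics()].
#' @param threshold efficiency threshold; retention requires
#'   `efficiency > threshold` (strictly).
#' @param scope `"fly"` (exclude whole flies) or `"episode"` (exclude
#'   fly-by-episode records).
#' @return A list with `retained` (fly ids, or a filtered metrics table for
#'   episode scope), `failures` (a log of sub-threshold records) and
#'   `unconstrained` (records with zero baseline SD-window sleep).
#' @export
apply_efficiency_filter <- function(metrics, threshold = 0.9,
                                    scope = c("fly", "episode")) {
  scope <- match.arg(scope)
  dt <- data.table::as.data.table(metrics)
  constrained <- dt[baseline_sleep_sd_window > 0]
  failures <- constrained[efficiency <= threshold,
                          .(fly_id, episode_index, efficiency)]
  unconstrained <- dt[baseline_sleep_sd_window == 0, .(fly_id, episode_index)]
  if (scope == "fly") {
    retained <- setdiff(unique(dt$fly_id), unique(failures$fly_id))
    list(retained = retained, failures = failures[],
         unconstrained = unconstrained[])
  } else {
    keep <- dt[baseline_sleep_sd_window == 0 | efficiency > threshold]
    list(retained = keep[], failures = failures[],
         unconstrained = unconstrained[])
  }
}

#' Percent of lost sleep recovered
#'
#' `100 * sleep_gain / sleep_lost` where sleep lost is positive; undefined
#' (NA) otherwise, guarding the division rather than dropping records.
#'
#' @param metrics output of [episode_metrics()].
#' @return `metrics` with an added `percent_recovered` column.
#' @export
percent_recovered <- function(metrics) {
  dt <- data.table::as.data.table(metrics)
  dt[, percent_recovered := ifelse(sleep_lost > 0,
                                   100 * sleep_gain / sleep_lost, NA_real_)]
  dt[]
}

#' Cohort summary of episode metrics by rebound onset
#'
#' Mean, SEM (`sd/sqrt(n)`) and n over flies for each rebound-onset ZT.
#' Single-fly groups have `NA` SEM.
#'
#' @param metrics output of [episode_metrics()] (optionally pre-filtered).
#' @param retained optional fly ids to keep (e.g. from
#'   [apply_efficiency_filter()]).
#' @param onset_zt optional onset ZTs to summarize; default all.
#' @return A `data.table` keyed by `onset_zt` with `n` and mean/SEM columns
#'   for sleep gain, sleep lost, rebound sleep, baseline rebound-window
#'   sleep and latency.
#' @export
cohort_summary <- function(metrics, retained = NULL, onset_zt = NULL) {
  dt <- data.table::as.data.table(metrics)
  if (!is.null(retained)) dt <- dt[fly_id %in% retained]
  if (!is.null(onset_zt)) {
    keep_zt <- onset_zt
    dt <- dt[sapply(dt$onset_zt, function(z) any(abs(z - keep_zt) < 1e-9))]
  }
  if (!nrow(dt)) stop("empty cohort: no metrics to summarize", call. = FALSE)
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  out <- dt[, .(
    n = .N,
    gain_mean = mean(sleep_gain), gain_sem = sem(sleep_gain),
    lost_mean = mean(sleep_lost), lost_sem = sem(sleep_lost),
    rebound_mean = mean(rebound_sleep), rebound_sem = sem(rebound_sleep),
    baseline_rebound_mean = mean(baseline_sleep_rebound_window),
    baseline_rebound_sem = sem(baseline_sleep_rebound_window),
    latency_mean = mean(latency), latency_sem = sem(latency)
  ), by = onset_zt]
  data.table::setkey(out, onset_zt)
  out[]
}
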