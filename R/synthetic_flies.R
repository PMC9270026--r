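#' Configuration for the synthetic fly cohort generator
#'
#' The generator is a two-process, bout-based (alternating renewal) model of
#' fly sleep at one-minute resolution. A circadian gate `C(zt)` with wake
#' peaks at lights-on (ZT0) and lights-off (ZT12) lengthens wake bouts around
#' the activity peaks; a homeostatic pressure `P` accumulates during wake
#' (`alpha` per wake minute), decays multiplicatively during sleep (`beta`
#' per sleep minute) and biases the bout means toward sleep through `weight`.
#' Sleep bouts have a hard 5-minute floor and wake minutes always emit at
#' least one beam crossing, so scored sleep on simulated data equals the
#' simulated inactive time exactly - the identity the recovery tests rest on.
#'
#' During deprivation windows each minute is independently forced awake with
#' probability `sd_efficacy`, abstracting the ~20 s vibration train. In
#' `"gain_injection"` mode, rebound windows whose onset ZT appears in
#' `gain_profile` are re-weighted so their expected scored sleep equals
#' `B(zt) + g(zt)`, where `B(zt)` is the mechanistic model's expected
#' baseline sleep in that clock window (see [expected_baseline_sleep()]);
#' the pipeline's expected measured sleep gain there is then exactly `g(zt)`.
#'
#' @param n_flies cohort size (one DAM channel each).
#' @param seed integer master seed; each fly gets an independent substream
#'   derived from `(seed, fly)`, so growing the cohort does not perturb
#'   existing flies.
#' @param mode `"mechanistic"` (pure two-process model everywhere) or
#'   `"gain_injection"` (profiled rebound windows overridden).
#' @param gate list: `floor` (baseline wake drive), `morning_peak`,
#'   `evening_peak` (peak heights at ZT0/ZT12), `morning_sigma`,
#'   `evening_sigma` (peak widths, hours).
#' @param homeostat list: `alpha` (pressure gain per wake minute), `beta`
#'   (fractional decay per sleep minute), `weight` (coupling into bout
#'   means), `p0` (initial pressure).
#' @param bouts list: `wake_mean0`, `sleep_mean0` - base bout means in
#'   minutes before circadian/homeostatic modulation.
#' @param activity_rate Poisson rate of extra counts per wake minute (each
#'   wake minute emits `1 + Poisson(activity_rate)` crossings).
#' @param sd_efficacy per-minute probability of forced wakefulness during a
#'   deprivation window, in `[0, 1]`.
#' @param gain_profile `data.frame` with columns `zt` and `gain` (minutes):
#'   injected expected sleep gain for rebound windows starting at those
#'   onset ZTs. Defaults to [default_gain_profile()]. Episodes whose onset
#'   is not listed stay on the mechanistic process.
#' @param baseline_estimator list: `n_flies`, `n_days`, `seed` controlling
#'   the fixed-seed simulation that estimates `B(zt)` for gain injection.
#' @return A validated `ssd_sim_config` object.
#' @export
sim_config <- function(n_flies = 32L, seed = 1L,
                       mode = c("mechanistic", "gain_injection"),
                       gate = list(), homeostat = list(), bouts = list(),
                       activity_rate = 2, sd_efficacy = 0.99,
                       gain_profile = default_gain_profile(),
                       baseline_estimator = list()) {
  mode <- match.arg(mode)
  gate <- utils::modifyList(
    list(floor = 0.25, morning_peak = 1.8, evening_peak = 1.3,
         morning_sigma = 2.6, evening_sigma = 1.5), gate)
  homeostat <- utils::modifyList(
    list(alpha = 1, beta = 0.03, weight = 0.005, p0 = 30), homeostat)
  bouts <- utils::modifyList(list(wake_mean0 = 60, sleep_mean0 = 18), bouts)
  baseline_estimator <- utils::modifyList(
    list(n_flies = 256L, n_days = 2L, seed = 8191L), baseline_estimator)
  cfg <- structure(
    list(n_flies = as.integer(n_flies), seed = as.integer(seed), mode = mode,
         gate = gate, homeostat = homeostat, bouts = bouts,
         activity_rate = activity_rate, sd_efficacy = sd_efficacy,
         gain_profile = as.data.frame(gain_profile),
         baseline_estimator = baseline_estimator),
    class = "ssd_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_flies < 1L) stop("config error: n_flies must be >= 1", call. = FALSE)
  if (cfg$activity_rate <= 0)
    stop("config error: activity_rate must be > 0 so wake minutes score >= 1 count",
         call. = FALSE)
  if (cfg$sd_efficacy < 0 || cfg$sd_efficacy > 1)
    stop("config error: sd_efficacy must lie in [0, 1]", call. = FALSE)
  with(cfg$gate, if (floor <= 0 || morning_peak < 0 || evening_peak < 0 ||
                     morning_sigma <= 0 || evening_sigma <= 0)
    stop("config error: gate parameters out of range", call. = FALSE))
  with(cfg$homeostat, if (alpha < 0 || beta < 0 || beta >= 1 || weight < 0)
    stop("config error: homeostat parameters out of range", call. = FALSE))
  with(cfg$bouts, if (wake_mean0 <= 0 || sleep_mean0 <= 0)
    stop("config error: bout means must be positive", call. = FALSE))
  gp <- cfg$gain_profile
  if (nrow(gp) && (!all(c("zt", "gain") %in% names(gp)) ||
                   any(gp$zt < 0 | gp$zt >= 24)))
    stop("config error: gain_profile needs zt in [0, 24) and gain columns",
         call. = FALSE)
  invisible(cfg)
}

#' Default injected gain profile
#'
#' Places a large morning rebound gain (133 min at ZT1.5) and a much smaller
#' evening gain (51 min at ZT9.5), the cohort-level morning/evening rebound
#' asymmetry the analysis is designed to detect.
#'
#' @return A `data.frame` with columns `zt` and `gain`.
#' @export
default_gain_profile <- function() {
  data.frame(zt = c(1.5, 9.5), gain = c(133, 51))
}

#' Circadian wake gate
#'
#' Nonnegative wake drive with circular Gaussian peaks at ZT0 (morning) and
#' ZT12 (evening) over a constant floor.
#'
#' @param zt zeitgeber time(s) in hours.
#' @param gate gate parameter list (see [sim_config()]).
#' @return Numeric wake drive, same length as `zt`.
#' @export
circadian_gate <- function(zt, gate) {
  d0 <- pmin(zt %% 24, 24 - zt %% 24)
  d12 <- abs(zt %% 24 - 12)
  gate$floor +
    gate$morning_peak * exp(-d0^2 / (2 * gate$morning_sigma^2)) +
    gate$evening_peak * exp(-d12^2 / (2 * gate$evening_sigma^2))
}

fly_substream_seed <- function(seed, fly) {
  as.integer((abs(seed) %% 100000L) * 10007L + fly * 7919L) %% 2147483646L + 1L
}

#' Simulate a cohort of synthetic flies
#'
#' Generates per-minute beam-crossing counts for `n_flies` over `n_days`,
#' with the recording starting at ZT0. Outside deprivation windows flies
#' alternate wake and sleep bouts drawn from the two-process bout model;
#' each wake minute emits `1 + Poisson(activity_rate)` counts and each sleep
#' minute emits 0. During deprivation windows minutes are forced awake with
#' probability `sd_efficacy`. In gain-injection mode, profiled rebound
#' windows are replaced by a bout pattern whose expected sleep equals
#' `B(onset_zt) + g(onset_zt)` (see [sim_config()]).
#'
#' @param config an `ssd_sim_config`.
#' @param schedule an `ssd_schedule`, or `NULL` for undisturbed baseline
#'   recording.
#' @param n_days recording length in days; defaults to the days needed to
#'   cover the schedule (or 3 baseline days without one).
#' @return An activity table (`fly_id`, `t`, `zt`, `count`), keyed by fly
#'   and minute; reproducible given `config$seed`.
#' @export
simulate_cohort <- function(config, schedule = NULL, n_days = NULL) {
  validate_sim_config(config)
  if (is.null(n_days))
    n_days <- if (is.null(schedule)) 3L else schedule_days(schedule)
  n_min <- as.integer(n_days) * MIN_PER_DAY
  sd_windows <- NULL
  overrides <- NULL
  if (!is.null(schedule)) {
    if (max(schedule$episodes$rebound_end_t) > n_min)
      stop("range error: schedule extends beyond the simulated recording",
           call. = FALSE)
    sd_windows <- schedule$episodes[, .(sd_start_t, sd_end_t)]
    if (config$mode == "gain_injection")
      overrides <- injection_targets(config, schedule)
  }
  zt_min <- (seq_len(n_min) - 1L) %% MIN_PER_DAY / 60
  gate_min <- circadian_gate(zt_min, config$gate)

  tabs <- vector("list", config$n_flies)
  for (fly in seq_len(config$n_flies)) {
    set.seed(fly_substream_seed(config$seed, fly))
    asleep <- simulate_fly_states(config, n_min, gate_min, sd_windows, overrides)
    counts <- integer(n_min)
    wake <- !asleep
    counts[wake] <- 1L + stats::rpois(sum(wake), config$activity_rate)
    tabs[[fly]] <- data.table::data.table(
      fly_id = sprintf("fly%03d", fly),
      t = seq_len(n_min) - 1L, zt = zt_min, count = counts)
  }
  out <- data.table::rbindlist(tabs)
  data.table::setkey(out, fly_id, t)
  out[]
}

# Resolve gain-injection targets: per profiled episode, the absolute
# expected window sleep T = B(onset_zt) + g(onset_zt).
injection_targets <- function(config, schedule) {
  gp <- config$gain_profile
  if (!nrow(gp)) return(NULL)
  ep <- schedule$episodes
  hits <- lapply(seq_len(nrow(gp)), function(i) {
    rows <- which(abs(ep$onset_zt - gp$zt[i]) < 1e-9)
    if (!length(rows)) return(NULL)
    B <- expected_baseline_sleep(config, c(gp$zt[i], gp$zt[i] + REBOUND_MINUTES / 60))
    target <- B + gp$gain[i]
    if (target < 0 || target > REBOUND_MINUTES)
      stop(sprintf(
        "config error: infeasible gain %g at ZT%.2f (baseline %.1f min of %d)",
        gp$gain[i], gp$zt[i], B, REBOUND_MINUTES), call. = FALSE)
    data.table::data.table(start = ep$sd_end_t[rows], end = ep$rebound_end_t[rows],
                           target = target)
  })
  out <- data.table::rbindlist(hits)
  if (nrow(out)) out[order(start)] else NULL
}

# One fly's minute-resolution sleep/wake state sequence. The RNG stream is
# consumed in a fixed order: SD forcing Bernoullis, then injected window
# patterns (episode order), then bout draws as the trajectory unfolds.
simulate_fly_states <- function(config, n_min, gate_min, sd_windows, overrides) {
  forced <- rep(NA_integer_, n_min)  # NA free, 0 forced wake, 1 forced sleep
  if (!is.null(sd_windows) && nrow(sd_windows)) {
    for (i in seq_len(nrow(sd_windows))) {
      idx <- (sd_windows$sd_start_t[i] + 1L):sd_windows$sd_end_t[i]
      hit <- stats::runif(length(idx)) < config$sd_efficacy
      forced[idx[hit]] <- 0L
    }
  }
  if (!is.null(overrides) && nrow(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      idx <- (overrides$start[i] + 1L):overrides$end[i]
      forced[idx] <- injected_pattern(overrides$target[i],
                                      length(idx))
    }
  }

  hm <- config$homeostat
  bt <- config$bouts
  asleep <- logical(n_min)
  P <- hm$p0
  state_sleep <- FALSE
  rem <- 0L
  for (t in seq_len(n_min)) {
    fs <- forced[t]
    if (!is.na(fs)) {
      state_sleep <- fs == 1L
      rem <- 0L
    } else {
      if (rem <= 0L) {
        state_sleep <- !state_sleep
        C <- gate_min[t]
        drive <- 1 + hm$weight * P
        if (state_sleep) {
          mu <- min(5 + bt$sleep_mean0 * drive / C, 600)
          rem <- 5L + stats::rgeom(1L, 1 / (mu - 4))
        } else {
          mu <- max(bt$wake_mean0 * C / drive, 1.2)
          rem <- 1L + stats::rgeom(1L, 1 / mu)
        }
        rem <- min(rem, 720L)
      }
      rem <- rem - 1L
    }
    asleep[t] <- state_sleep
    P <- if (state_sleep) P * (1 - hm$beta) else P + hm$alpha
  }
  asleep
}

#' Sample total scored sleep for an injected rebound window
#'
#' Draws window sleep totals whose expectation equals `target` exactly while
#' respecting the 5-minute sleep-bout floor: for `target >= 5`,
#' `S = 5 + Binomial(window - 5, (target - 5)/(window - 5))`; below 5 the
#' draw is a 0/5 Bernoulli mixture with mean `target`.
#'
#' @param n number of draws.
#' @param target expected sleep minutes, in `[0, window]`.
#' @param window window length in minutes.
#' @return Integer vector of sleep totals, each 0 or in `[5, window]`.
#' @export
r_injected_window_sleep <- function(n, target, window = REBOUND_MINUTES) {
  if (target < 0 || target > window)
    stop("config error: target sleep must lie in [0, window]", call. = FALSE)
  if (target >= 5)
    5L + stats::rbinom(n, window - 5L, (target - 5) / (window - 5))
  else
    5L * (stats::runif(n) < target / 5)
}

# Realize a window sleep total as 0/1 minute states: k sleep bouts (each
# >= 5 min) separated by wake gaps, with the drawn total preserved exactly.
injected_pattern <- function(target, window) {
  S <- r_injected_window_sleep(1L, target, window)
  if (S == 0L) return(rep(0L, window))
  k_max <- S %/% 5L
  k <- max(1L, min(k_max, 1L + stats::rpois(1L, S / 75)))
  extra <- as.vector(stats::rmultinom(1L, S - 5L * k, rep(1, k)))
  bouts <- 5L + extra
  gaps <- as.vector(stats::rmultinom(1L, window - S, rep(1, k + 1L)))
  pattern <- integer(0)
  for (i in seq_len(k))
    pattern <- c(pattern, rep(0L, gaps[i]), rep(1L, bouts[i]))
  c(pattern, rep(0L, gaps[k + 1L]))
}

# Cache for baseline window-sleep expectations, keyed by the mechanistic
# parameters, the estimator settings and the window.
.baseline_cache <- new.env(parent = emptyenv())

#' Expected baseline sleep of the mechanistic model in a clock window
#'
#' Estimates, by long-run simulation at a fixed seed, the expected scored
#' sleep of an undisturbed fly in a given clock window per 24 h day. The
#' window is evaluated circularly within each day, matching how baseline
#' reference sleep is computed by [episode_metrics()]. This is the `B(zt)`
#' used to calibrate gain injection.
#'
#' @param config an `ssd_sim_config`; only the mechanistic parameters and
#'   `baseline_estimator` settings are used (the cohort seed is not, so the
#'   estimate is a deterministic function of the model).
#' @param clock_window numeric `c(zt_start, zt_end)` in hours; `zt_end` may
#'   exceed 24 for windows wrapping past midnight.
#' @return Expected sleep minutes in the window (scalar).
#' @export
expected_baseline_sleep <- function(config, clock_window) {
  est <- config$baseline_estimator
  key <- paste(collapse = "|", c(
    unlist(config$gate), unlist(config$homeostat), unlist(config$bouts),
    config$activity_rate, unlist(est), round(clock_window * 60)))
  hit <- get0(key, envir = .baseline_cache)
  if (!is.null(hit)) return(hit)
  base_cfg <- config
  base_cfg$mode <- "mechanistic"
  base_cfg$n_flies <- as.integer(est$n_flies)
  base_cfg$seed <- as.integer(est$seed)
  tab <- simulate_cohort(base_cfg, schedule = NULL, n_days = est$n_days)
  series <- score_sleep(tab)
  off <- clock_window_offsets(clock_window)
  val <- series[(t %% MIN_PER_DAY) %in% off,
                .(s = sum(asleep)), by = .(fly_id, day = t %/% MIN_PER_DAY)
                ][, mean(s)]
  assign(key, val, envir = .baseline_cache)
  val
}
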