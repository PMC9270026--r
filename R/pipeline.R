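#' Run the full simulate/score/analyze pipeline
#'
#' Chains the pipeline end to end: build (or load) a deprivation schedule,
#' simulate a synthetic cohort or read DAM monitor files, score sleep,
#' compute per-episode rebound metrics, apply the deprivation-efficiency
#' filter, summarize by rebound onset, build the rebound and baseline
#' heatmaps, select matched morning/evening onsets, and run the paired and
#' trend tests. Results are written to `out_dir` as plain-text artifacts:
#' `metrics.csv`, `summary.csv`, `heatmap.csv`, `baseline_profile.csv`,
#' `stats.json` and a `manifest.json` that records the seed, configuration
#' and package version so a run can be reconstructed exactly.
#'
#' @param config a named list, or path to a YAML/JSON file with the same
#'   structure. Recognized fields (all optional): `seed`, `n_flies`,
#'   `mode` (`"mechanistic"`/`"gain_injection"`), `sim` (overrides passed
#'   to [sim_config()]), `schedule` (list with `mode` `"full"`/`"abridged"`
#'   and optionally `first_onset_zt`, `n_episodes`, `zt0_minute`),
#'   `dam_files` + `lights_on` (analyze recorded monitors instead of
#'   simulating), `filter_threshold`, `filter_scope`, `match` (tolerances),
#'   `out_dir`.
#' @return Invisibly, a list with the schedule, metrics, filter result,
#'   summary, heatmaps, matched pair and test results.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(list(
    seed = 1L, n_flies = 32L, mode = "mechanistic", sim = list(),
    schedule = list(mode = "full"), dam_files = NULL,
    lights_on = "08:00:00", filter_threshold = 0.9, filter_scope = "fly",
    match = list(tol_baseline = 30, tol_lost = 30),
    out_dir = NULL), config)

  sched_args <- cfg$schedule
  schedule <- if (identical(sched_args$mode, "abridged"))
    make_abridged_ssd(zt0_minute = sched_args$zt0_minute %||% 2880L)
  else
    make_full_ssd(first_onset_zt = sched_args$first_onset_zt %||% 4.5,
                  n_episodes = sched_args$n_episodes %||% 24L,
                  zt0_minute = sched_args$zt0_minute %||% 2880L)

  if (!is.null(cfg$dam_files)) {
    missing_files <- cfg$dam_files[!file.exists(cfg$dam_files)]
    if (length(missing_files))
      stop("stage dam_io: DAM file not found: ", missing_files[1], call. = FALSE)
    tabs <- lapply(cfg$dam_files, read_dam, lights_on = cfg$lights_on)
    table <- data.table::rbindlist(tabs)
    data.table::setkey(table, fly_id, t)
    sim <- NULL
  } else {
    sim <- do.call(sim_config, utils::modifyList(
      list(n_flies = cfg$n_flies, seed = cfg$seed, mode = cfg$mode), cfg$sim))
    table <- simulate_cohort(sim, schedule)
  }

  series <- score_sleep(table)
  metrics <- episode_metrics(series, schedule)
  filt <- apply_efficiency_filter(metrics, threshold = cfg$filter_threshold,
                                  scope = cfg$filter_scope)
  retained <- if (cfg$filter_scope == "fly") filt$retained
  else unique(filt$retained$fly_id)
  if (!length(retained))
    stop("stage filter: no flies pass the efficiency filter", call. = FALSE)
  summary_tab <- cohort_summary(metrics, retained = retained)
  heat <- rebound_heatmap(series, schedule, retained = retained)
  base_prof <- baseline_heatmap(series, schedule$baseline_day_starts)

  pair <- match_morning_evening(summary_tab,
                                tol_baseline = cfg$match$tol_baseline %||% 30,
                                tol_lost = cfg$match$tol_lost %||% 30)
  paired <- NULL
  if (isTRUE(pair$matched)) {
    gm <- metrics[fly_id %in% retained & abs(onset_zt - pair$morning_zt) < 1e-9]
    ge <- metrics[fly_id %in% retained & abs(onset_zt - pair$evening_zt) < 1e-9]
    common <- intersect(gm$fly_id, ge$fly_id)
    paired <- paired_comparison(
      gm[match(common, fly_id)]$sleep_gain,
      ge[match(common, fly_id)]$sleep_gain)
  }
  ep_means <- metrics[fly_id %in% retained,
                      .(gain = mean(sleep_gain)), by = episode_index][order(episode_index)]
  trend <- if (nrow(ep_means) >= 3L) gain_trend(ep_means$gain, ep_means$episode_index)
  else NULL

  res <- list(schedule = schedule, metrics = metrics, filter = filt,
              retained = retained, summary = summary_tab, heatmap = heat,
              baseline_profile = base_prof, matched_pair = pair,
              paired_test = paired, trend = trend)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$out_dir, f)
    data.table::fwrite(metrics[order(fly_id, episode_index)], out("metrics.csv"))
    data.table::fwrite(summary_tab, out("summary.csv"))
    heatmap_to_csv(heat, out("heatmap.csv"))
    data.table::fwrite(base_prof$values, out("baseline_profile.csv"))
    jsonlite::write_json(
      list(matched_pair = pair, paired_test = paired, trend = trend,
           n_retained = length(retained),
           n_excluded = length(unique(metrics$fly_id)) - length(retained)),
      out("stats.json"), auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(
      list(package = "sleepssd",
           version = as.character(utils::packageVersion("sleepssd")),
           seed = cfg$seed,
           config = cfg[setdiff(names(cfg), "out_dir")]),
      out("manifest.json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(res)
}
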