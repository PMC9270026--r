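# Single-episode schedule: SD at t 3000-3150 (ZT2-4.5), rebound 3150-3420
# (ZT4.5-9), baseline days at t 0 and 1440.
one_ep_schedule <- function() make_full_ssd(n_episodes = 1)

# Crafted deterministic cohort:
#   f01 sleeps 100 min in the SD clock window and 60 min in the rebound
#       clock window on both baseline days, 5 min during SD, 60 min during
#       rebound -> lost 95, efficiency 0.95, gain 0, latency 50.
#   f02 same baselines but fully awake during SD and rebound
#       -> lost 100, efficiency 1, gain -60, latency censored.
crafted_series <- function() {
  n <- 3 * 1440
  base_iv <- list(c(120, 220), c(270, 330), c(1560, 1660), c(1710, 1770))
  f1 <- trace_with_sleep(n, c(base_iv, list(c(3100, 3105), c(3200, 3260))))
  f2 <- trace_with_sleep(n, base_iv)
  score_sleep(make_cohort_table(list(f1, f2)))
}

test_that("sleep lost, gain, efficiency and latency follow the window arithmetic", {
  met <- episode_metrics(crafted_series(), one_ep_schedule())
  m1 <- met[fly_id == "f01"]
  expect_equal(m1$baseline_sleep_sd_window, 100)
  expect_equal(m1$baseline_sleep_rebound_window, 60)
  expect_equal(m1$sd_sleep, 5)
  expect_equal(m1$sleep_lost, 95)
  expect_equal(m1$efficiency, 0.95)
  expect_equal(m1$rebound_sleep, 60)
  expect_equal(m1$sleep_gain, 0)
  expect_equal(m1$latency, 50L)
  expect_false(m1$latency_censored)
  expect_equal(m1$onset_zt, 4.5)

  m2 <- met[fly_id == "f02"]
  expect_equal(m2$sleep_lost, 100)
  expect_equal(m2$efficiency, 1)
  expect_equal(m2$sleep_gain, -60)
  expect_true(m2$latency_censored)
  expect_equal(m2$latency, 270L)

  # identity: sleep_lost + SD-window sleep = baseline SD-window sleep
  expect_equal(met$sleep_lost + met$sd_sleep, met$baseline_sleep_sd_window)
})

test_that("baseline clock windows wrap circularly within the baseline days", {
  # episode with onset ZT1.5: SD spans ZT23-ZT1.5, wrapping past midnight
  sched <- make_full_ssd(first_onset_zt = 1.5, n_episodes = 1)
  ep <- sched$episodes
  expect_equal(ep$onset_zt, 1.5)
  n <- schedule_days(sched) * 1440
  # sleep ZT23:20-23:50 and ZT0:10-0:40 on each baseline day (60 min inside
  # the wrapped SD clock window ZT23-ZT1.5), awake otherwise
  iv <- list(c(1400, 1430), c(10, 40), c(1440 + 1400, 1440 + 1430), c(1450, 1480))
  ser <- score_sleep(make_table(trace_with_sleep(n, iv)))
  met <- episode_metrics(ser, sched)
  expect_equal(met$baseline_sleep_sd_window, 60)
  expect_equal(met$sleep_lost, 60)
})

test_that("metrics require coverage of baseline days and episodes", {
  short <- score_sleep(make_table(rep(1L, 2000)))
  expect_error(episode_metrics(short, one_ep_schedule()), "range")
})

fake_metrics <- function(eff_by_fly, baseline = 100) {
  data.table::rbindlist(lapply(names(eff_by_fly), function(f) {
    eff <- eff_by_fly[[f]]
    data.table::data.table(
      fly_id = f, episode_index = seq_along(eff) - 1L,
      onset_zt = 4.5, baseline_sleep_sd_window = baseline,
      efficiency = if (baseline > 0) eff else NA_real_)
  }))
}

test_that("the efficiency filter excludes flies failing any constrained episode", {
  met <- fake_metrics(list(good = c(0.95, 0.97, 0.99), bad = c(0.95, 0.80, 0.99)))
  res <- apply_efficiency_filter(met, threshold = 0.9)
  expect_equal(res$retained, "good")
  expect_equal(res$failures$fly_id, "bad")
  expect_equal(res$failures$efficiency, 0.80)
})

test_that("episodes with zero baseline SD-window sleep impose no constraint", {
  met <- fake_metrics(list(f = c(0.95, 0.99)))
  vac <- data.table::data.table(
    fly_id = "f", episode_index = 2L, onset_zt = 11.5,
    baseline_sleep_sd_window = 0, efficiency = NA_real_)
  res <- apply_efficiency_filter(rbind(met, vac), threshold = 0.9)
  expect_equal(res$retained, "f")
  expect_equal(nrow(res$unconstrained), 1L)
})

test_that("episode-scoped filtering keeps passing records of failing flies", {
  met <- fake_metrics(list(a = c(0.95, 0.80)))
  res <- apply_efficiency_filter(met, scope = "episode")
  expect_equal(res$retained$episode_index, 0L)
})

test_that("raising the threshold never enlarges the retained set", {
  set.seed(606)
  met <- fake_metrics(setNames(
    lapply(1:20, function(i) runif(6, 0.5, 1)), sprintf("f%02d", 1:20)))
  prev <- NULL
  for (thr in seq(0.5, 0.99, by = 0.07)) {
    cur <- apply_efficiency_filter(met, threshold = thr)$retained
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("percent recovered guards the division by zero sleep lost", {
  met <- data.table::data.table(sleep_gain = c(95, 0, 30), sleep_lost = c(95, 120, 0))
  out <- percent_recovered(met)
  expect_equal(out$percent_recovered, c(100, 0, NA))
})

test_that("cohort summary reports mean, SEM and n per onset", {
  met <- data.table::data.table(
    fly_id = c("a", "b", "c"), episode_index = 0L, onset_zt = 4.5,
    sleep_gain = c(10, 20, 30), sleep_lost = 5, rebound_sleep = 100,
    baseline_sleep_rebound_window = 90, latency = 3L)
  s <- cohort_summary(met)
  expect_equal(s$n, 3L)
  expect_equal(s$gain_mean, 20)
  expect_equal(s$gain_sem, 10 / sqrt(3))
  expect_equal(s$lost_sem, 0)

  single <- cohort_summary(met[1])
  expect_true(is.na(single$gain_sem))
  expect_error(cohort_summary(met, retained = character(0)), "empty")
})
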