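test_that("observed heatmap rows equal cohort means and complete grids need no interpolation", {
  sh <- shared_abridged()
  h <- rebound_heatmap(sh$series, sh$schedule)
  expect_equal(sum(h$observed), 5L)
  expect_equal(length(h$zt), 24L)
  expect_true(all(h$values >= 0 & h$values <= 30 + 1e-9))

  # observed rows match a direct windowed recount
  ep <- sh$schedule$episodes
  for (i in seq_len(nrow(ep))) {
    r <- which(abs(h$zt - ep$onset_zt[i]) < 1e-9)
    direct <- vapply(0:8, function(j) {
      w <- c(ep$sd_end_t[i] + j * 30L, ep$sd_end_t[i] + (j + 1L) * 30L)
      mean(sleep_in_window(sh$series, w)$sleep_min)
    }, numeric(1))
    expect_equal(unname(h$values[r, ]), direct)
  }

  full <- make_full_ssd()
  cfg <- sim_config(n_flies = 4, seed = 9)
  ser <- score_sleep(simulate_cohort(cfg, full))
  hf <- rebound_heatmap(ser, full)
  expect_true(all(hf$observed))
  expect_equal(length(hf$zt), 24L)
})

test_that("missing rows are filled by circular linear interpolation of observed rows", {
  obs <- rbind(rep(10, 9), rep(20, 9))
  # observed at ZT2.5 and ZT4.5; ZT3.5 is the midpoint
  mid <- sleepssd:::circ_interp_row(3.5, c(2.5, 4.5), obs, wrap = TRUE)
  expect_equal(mid, rep(15, 9))
  # wrap-around: between ZT22.5 (=10) and ZT2.5 (=20) the ZT0.5 point is
  # 2/4 of the way
  wrapd <- sleepssd:::circ_interp_row(0.5, c(2.5, 22.5), rbind(rep(20, 9), rep(10, 9)),
                                      wrap = TRUE)
  expect_equal(wrapd, rep(15, 9))
  # clamped mode extends the edge value instead
  clamp <- sleepssd:::circ_interp_row(0.5, c(2.5, 22.5), rbind(rep(20, 9), rep(10, 9)),
                                      wrap = FALSE)
  expect_equal(clamp, rep(20, 9))

  sh <- shared_abridged()
  h <- rebound_heatmap(sh$series, sh$schedule)
  stored_obs <- h$values[h$observed, ]
  h2 <- rebound_heatmap(sh$series, sh$schedule, wrap = FALSE)
  expect_equal(h2$values[h2$observed, ], stored_obs)  # interpolation mode never touches observed rows
  expect_false(any(is.na(h$values)))
})

test_that("the baseline heatmap band equals the baseline sleep profile", {
  sh <- shared_abridged()
  a <- baseline_heatmap(sh$series, sh$schedule$baseline_day_starts)
  b <- baseline_sleep_profile(sh$series, sh$schedule$baseline_day_starts)
  expect_equal(a$values, b$values)
  # order invariance over flies
  shuf <- sh$series[order(rev(fly_id), t)]
  expect_equal(baseline_heatmap(shuf, sh$schedule$baseline_day_starts)$values,
               a$values)
})

fake_summary <- function(zt, baseline, lost) {
  data.table::data.table(onset_zt = zt, baseline_rebound_mean = baseline,
                         lost_mean = lost)
}

test_that("morning/evening matching minimizes the standardized confound deltas", {
  s <- fake_summary(c(1.5, 8.5, 9.5), baseline = c(100, 100, 140),
                    lost = c(50, 52, 90))
  m <- match_morning_evening(s, tol_baseline = 50, tol_lost = 50)
  expect_true(m$matched)
  expect_equal(m$morning_zt, 1.5)
  expect_equal(m$evening_zt, 8.5)

  # exact-baseline candidate wins
  s2 <- fake_summary(c(2.5, 8.5, 10.5), baseline = c(120, 120, 119),
                     lost = c(60, 60, 60))
  m2 <- match_morning_evening(s2)
  expect_equal(m2$evening_zt, 8.5)

  none <- match_morning_evening(
    fake_summary(c(1.5, 9.5), c(50, 200), c(10, 200)),
    tol_baseline = 5, tol_lost = 5)
  expect_false(none$matched)
  expect_match(none$reason, "tolerance")
})

test_that("matching equals exhaustive search on random instances", {
  set.seed(808)
  for (i in 1:30) {
    nm <- sample(1:4, 1); ne <- sample(1:4, 1)
    s <- fake_summary(c(runif(nm, 0, 6), runif(ne, 6, 12)),
                      baseline = runif(nm + ne, 50, 250),
                      lost = runif(nm + ne, 20, 140))
    res <- match_morning_evening(s, tol_baseline = Inf, tol_lost = Inf)
    cand <- s[order(onset_zt)]
    ms <- cand[onset_zt < 6]; es <- cand[onset_zt >= 6]
    sb <- stats::sd(cand$baseline_rebound_mean); sl <- stats::sd(cand$lost_mean)
    best <- Inf; best_pair <- NULL
    for (a in seq_len(nrow(ms))) for (b in seq_len(nrow(es))) {
      sc <- abs(ms$baseline_rebound_mean[a] - es$baseline_rebound_mean[b]) / sb +
        abs(ms$lost_mean[a] - es$lost_mean[b]) / sl
      if (sc < best - 1e-12) {
        best <- sc
        best_pair <- c(ms$onset_zt[a], es$onset_zt[b])
      }
    }
    expect_equal(c(res$morning_zt, res$evening_zt), best_pair)
  }
})

test_that("paired comparison matches the textbook t statistic and flags degeneracy", {
  x <- c(5, 7, 9, 6); y <- c(3, 4, 8, 2)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  res <- paired_comparison(x, y)
  expect_false(res$degenerate)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 3))

  expect_true(paired_comparison(c(1, 2, 3), c(0, 1, 2))$degenerate)
  expect_true(paired_comparison(c(2, 2), c(2, 2))$degenerate)
  expect_true(paired_comparison(numeric(0), numeric(0))$degenerate)
})

test_that("group comparison reproduces the one-way ANOVA decomposition and Tukey pairs", {
  g1 <- c(1, 2, 3); g2 <- c(2, 3, 4); g3 <- c(6, 7, 8)
  values <- c(g1, g2, g3)
  groups <- rep(c("a", "b", "c"), each = 3)
  res <- group_comparison(values, groups)
  # hand sums of squares
  gm <- mean(values)
  ss_b <- 3 * sum((c(mean(g1), mean(g2), mean(g3)) - gm)^2)
  ss_w <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) + sum((g3 - mean(g3))^2)
  f_hand <- (ss_b / 2) / (ss_w / 6)
  expect_equal(res$F, f_hand)
  expect_equal(nrow(res$tukey), 3L)

  # two groups: F equals the squared unpaired t
  a <- c(4, 6, 8, 5); b <- c(9, 11, 10, 12)
  res2 <- group_comparison(c(a, b), rep(c("a", "b"), each = 4))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2)

  ident <- group_comparison(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(ident$F, 0)
  expect_true(all(ident$tukey$p_adj > 0.99))

  flat <- group_comparison(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_true(flat$degenerate)
})

test_that("gain trend recovers exact slopes and needs three points", {
  expect_equal(gain_trend(rep(12, 6))$slope, 0)
  res <- gain_trend(c(0, 1, 2, 3))
  expect_equal(res$slope, 1)
  expect_error(gain_trend(c(1, 2)), "3 episodes")
})
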