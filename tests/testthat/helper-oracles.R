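# Shared fixtures and independent oracles, built in code at test time.

# Build a single-fly activity table from a count vector.
make_table <- function(counts, fly = "f1", t0 = 0L, zt0 = 0) {
  n <- length(counts)
  data.table::data.table(
    fly_id = fly,
    t = t0 + seq_len(n) - 1L,
    zt = ((zt0 * 60 + t0 + seq_len(n) - 1L) %% 1440L) / 60,
    count = as.integer(counts))
}

# Multi-fly table: one count vector per fly.
make_cohort_table <- function(count_list) {
  data.table::rbindlist(lapply(seq_along(count_list), function(i)
    make_table(count_list[[i]], fly = sprintf("f%02d", i))))
}

# Counts that are awake (1) everywhere except the given sleep intervals,
# each a c(start, end) half-open pair of 0-based minutes.
trace_with_sleep <- function(n, sleep_intervals) {
  counts <- rep(1L, n)
  for (iv in sleep_intervals)
    counts[(iv[1] + 1):iv[2]] <- 0L
  counts
}

# Independent sleep-scoring oracle: sliding-window convolution instead of
# run-length encoding. A minute is asleep iff it is covered by at least one
# window of `k` consecutive zero-count minutes.
oracle_score <- function(counts, k = 5L) {
  z <- as.numeric(counts == 0L)
  n <- length(z)
  if (n < k) return(rep(FALSE, n))
  trail <- stats::filter(z, rep(1, k), sides = 1)  # trail[i] = sum z[i-k+1..i]
  complete_end <- !is.na(trail) & trail == k
  covered <- rev(stats::filter(rev(as.numeric(complete_end)), rep(1, k), sides = 1))
  covered[is.na(covered)] <- vapply(which(is.na(covered)), function(i)
    sum(complete_end[i:min(n, i + k - 1L)]), numeric(1))
  as.logical(covered > 0)
}

# Deterministic small simulated cohort on the abridged schedule, shared by
# several analysis tests (computed lazily, once per test run).
shared_abridged <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sched <- make_abridged_ssd()
      cfg <- sim_config(n_flies = 8L, seed = 7L)
      tab <- simulate_cohort(cfg, sched, n_days = 6L)
      ser <- score_sleep(tab)
      cache <<- list(schedule = sched, config = cfg, table = tab,
                     series = ser,
                     metrics = episode_metrics(ser, sched))
    }
    cache
  }
})
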