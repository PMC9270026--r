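#' Rebound sleep heatmap with circular interpolation
#'
#' Builds the matrix of cohort mean sleep per 30-min post-deprivation bin
#' (columns, 9 bins over 4.5 h) by rebound-onset ZT (rows). Rows measured by
#' the schedule are cohort means and are never touched by interpolation;
#' onset ZTs missing from the schedule are filled by column-wise linear
#' interpolation along the ZT axis, treated circularly by default since ZT
#' is periodic (`wrap = FALSE` clamps at the observed extremes instead).
#'
#' @param series a sleep series covering the schedule.
#' @param schedule an `ssd_schedule`.
#' @param retained optional fly ids to include (e.g. after the efficiency
#'   filter).
#' @param bin_minutes post-SD bin width (must divide 270).
#' @param wrap interpolate circularly across the ZT24 -> 0 boundary.
#' @param grid_zt optional row grid; defaults to the 24 hourly values at the
#'   observed onsets' fractional offset when that offset is shared (e.g.
#'   0.5, 1.5, ..., 23.5), otherwise to the observed onsets only.
#' @return A `rebound_heatmap` object: list with `zt` (row onsets),
#'   `values` (rows x bins matrix of mean sleep minutes), `observed`
#'   (logical row mask), `bin_minutes`, `n_flies`.
#' @export
rebound_heatmap <- function(series, schedule, retained = NULL,
                            bin_minutes = 30L, wrap = TRUE, grid_zt = NULL) {
  ep <- schedule$episodes
  if (!nrow(ep)) stop("schedule has no episodes", call. = FALSE)
  if (REBOUND_MINUTES %% bin_minutes != 0L)
    stop("bin_minutes must divide ", REBOUND_MINUTES, call. = FALSE)
  dt <- check_sleep_series(series)
  if (!is.null(retained)) dt <- dt[fly_id %in% retained]
  if (!nrow(dt)) stop("empty cohort: no retained flies", call. = FALSE)
  A <- sleep_matrix(dt)
  t0 <- attr(A, "t0")
  n_bins <- REBOUND_MINUTES %/% bin_minutes

  obs <- t(vapply(seq_len(nrow(ep)), function(i) {
    base <- ep$sd_end_t[i] - t0
    vapply(seq_len(n_bins), function(j) {
      idx <- (base + (j - 1L) * bin_minutes + 1L):(base + j * bin_minutes)
      mean(colSums(A[idx, , drop = FALSE]))
    }, numeric(1))
  }, numeric(n_bins)))
  o <- order(ep$onset_zt)
  obs_zt <- ep$onset_zt[o]
  obs <- obs[o, , drop = FALSE]
  if (anyDuplicated(obs_zt)) {
    keep <- !duplicated(obs_zt)
    for (z in unique(obs_zt[duplicated(obs_zt)]))
      obs[which(obs_zt == z)[1], ] <- colMeans(obs[obs_zt == z, , drop = FALSE])
    obs <- obs[keep, , drop = FALSE]
    obs_zt <- obs_zt[keep]
  }

  if (is.null(grid_zt)) {
    frac <- unique(round(obs_zt %% 1, 9))
    grid_zt <- if (length(frac) == 1L) frac + 0:23 else obs_zt
  }
  grid_zt <- sort(unique(round(grid_zt, 9)))
  values <- matrix(NA_real_, nrow = length(grid_zt), ncol = n_bins)
  observed <- logical(length(grid_zt))
  for (r in seq_along(grid_zt)) {
    hit <- which(abs(obs_zt - grid_zt[r]) < 1e-9)
    if (length(hit)) {
      values[r, ] <- obs[hit, ]
      observed[r] <- TRUE
    }
  }
  miss <- which(!observed)
  for (r in miss)
    values[r, ] <- circ_interp_row(grid_zt[r], obs_zt, obs, wrap)

  structure(list(zt = grid_zt, values = values, observed = observed,
                 bin_minutes = as.integer(bin_minutes), n_flies = ncol(A)),
            class = "rebound_heatmap")
}

# Linear interpolation of one missing row from observed rows along a
# periodic (24 h) or clamped ZT axis.
circ_interp_row <- function(z, obs_zt, obs, wrap) {
  if (nrow(obs) == 1L) return(obs[1L, ])
  if (wrap) {
    ib <- which(obs_zt < z)
    ia <- which(obs_zt > z)
    if (length(ib)) {
      below <- max(obs_zt[ib]); rb <- which(obs_zt == below)[1]
    } else {
      below <- max(obs_zt) - 24; rb <- which.max(obs_zt)
    }
    if (length(ia)) {
      above <- min(obs_zt[ia]); ra <- which(obs_zt == above)[1]
    } else {
      above <- min(obs_zt) + 24; ra <- which.min(obs_zt)
    }
    w <- (z - below) / (above - below)
    (1 - w) * obs[rb, ] + w * obs[ra, ]
  } else {
    apply(obs, 2L, function(col)
      stats::approx(obs_zt, col, xout = z, rule = 2)$y)
  }
}

#' @export
print.rebound_heatmap <- function(x, ...) {
  cat(sprintf("rebound heatmap: %d onset rows (%d observed) x %d bins of %d min, n = %d flies\n",
              length(x$zt), sum(x$observed), ncol(x$values), x$bin_minutes,
              x$n_flies))
  invisible(x)
}

#' Export a rebound heatmap as a CSV matrix
#' @param heatmap a `rebound_heatmap`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
heatmap_to_csv <- function(heatmap, path) {
  m <- data.table::as.data.table(heatmap$values)
  data.table::setnames(m, sprintf("min_%d_%d",
                                  (seq_len(ncol(heatmap$values)) - 1L) * heatmap$bin_minutes,
                                  seq_len(ncol(heatmap$values)) * heatmap$bin_minutes))
  out <- data.table::data.table(onset_zt = heatmap$zt,
                                observed = heatmap$observed)
  data.table::fwrite(cbind(out, m), path)
  invisible(path)
}

#' Baseline heatmap band
#'
#' The lower band of the rebound/baseline display: mean sleep per clock bin
#' over the baseline days. Delegates to [baseline_sleep_profile()].
#'
#' @inheritParams baseline_sleep_profile
#' @return A `daily_profile` (see [baseline_sleep_profile()]).
#' @export
baseline_heatmap <- function(series, baseline_day_starts, bin_minutes = 30L) {
  baseline_sleep_profile(series, baseline_day_starts, bin_minutes)
}

#' Select baseline-matched morning and evening onsets
#'
#' Picks the morning/evening onset pair whose mean baseline rebound-window
#' sleep and mean sleep lost - the two confounds of a morning-vs-evening
#' rebound comparison - are most comparable. The objective is
#' `w1*|d_baseline|/s_b + w2*|d_lost|/s_l`, each delta standardized by the
#' spread of that quantity across candidate onsets; ties break toward the
#' smaller baseline delta, then the earlier morning ZT, then the earlier
#' evening ZT. A pair must also fall within the absolute tolerances.
#'
#' @param summary a per-onset summary from [cohort_summary()] (needs
#'   `onset_zt`, `baseline_rebound_mean`, `lost_mean`).
#' @param tol_baseline,tol_lost maximum admissible |delta| in minutes.
#' @param weights length-2 weights for the standardized baseline and lost
#'   deltas.
#' @param morning,evening half-open ZT ranges defining candidates.
#' @return A list with `matched`; when `TRUE` also `morning_zt`,
#'   `evening_zt`, `delta_baseline`, `delta_lost`, `score`; when `FALSE` a
#'   `reason` (an explicit no-match result, not an error).
#' @export
match_morning_evening <- function(summary, tol_baseline = 30, tol_lost = 30,
                                  weights = c(1, 1),
                                  morning = c(0, 6), evening = c(6, 12)) {
  s <- data.table::as.data.table(summary)
  m <- s[onset_zt >= morning[1] & onset_zt < morning[2]]
  e <- s[onset_zt >= evening[1] & onset_zt < evening[2]]
  if (!nrow(m) || !nrow(e))
    return(list(matched = FALSE, reason = "no morning or no evening candidates"))
  cand <- rbind(m, e)
  s_b <- stats::sd(cand$baseline_rebound_mean)
  s_l <- stats::sd(cand$lost_mean)
  if (!isTRUE(s_b > 0)) s_b <- 1
  if (!isTRUE(s_l > 0)) s_l <- 1
  pairs <- data.table::CJ(mi = seq_len(nrow(m)), ei = seq_len(nrow(e)))
  pairs[, delta_baseline := abs(m$baseline_rebound_mean[mi] -
                                  e$baseline_rebound_mean[ei])]
  pairs[, delta_lost := abs(m$lost_mean[mi] - e$lost_mean[ei])]
  pairs[, score := weights[1] * delta_baseline / s_b +
          weights[2] * delta_lost / s_l]
  ok <- pairs[delta_baseline <= tol_baseline & delta_lost <= tol_lost]
  if (!nrow(ok))
    return(list(matched = FALSE,
                reason = "no morning/evening pair within tolerances"))
  ok[, `:=`(morning_zt = m$onset_zt[mi], evening_zt = e$onset_zt[ei])]
  best <- ok[order(score, delta_baseline, morning_zt, evening_zt)][1]
  list(matched = TRUE, morning_zt = best$morning_zt,
       evening_zt = best$evening_zt, delta_baseline = best$delta_baseline,
       delta_lost = best$delta_lost, score = best$score)
}

#' Paired comparison of per-fly values at two time points
#'
#' Two-sided paired t-test with flies paired with themselves across time
#' points. Degenerate inputs (n < 2, or zero variance of the differences)
#' are flagged rather than raising.
#'
#' @param x,y equal-length paired samples (same fly order).
#' @return A list with `t`, `df`, `p`, `mean_diff`, `n`, `degenerate`.
#' @export
paired_comparison <- function(x, y) {
  if (length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  n <- length(x)
  d <- x - y
  if (n < 2L || isTRUE(all.equal(stats::sd(d), 0)) || stats::sd(d) == 0)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_diff = if (n) mean(d) else NA_real_, n = n,
                degenerate = TRUE))
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), n = n,
       degenerate = FALSE)
}

#' One-way group comparison with Tukey post hoc
#'
#' One-way ANOVA across groups followed by all-pairs comparisons with Tukey
#' HSD adjustment (the only multiplicity correction applied).
#'
#' @param values numeric outcomes.
#' @param groups group labels, same length as `values`; at least 2 groups
#'   with n >= 2 each.
#' @return A list with `F`, `df`, `p`, `tukey` (a `data.table` of pairwise
#'   `comparison`, `diff`, `p_adj`) and `degenerate`.
#' @export
group_comparison <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  if (all(tapply(values, groups, stats::sd) == 0)) {
    return(list(F = NA_real_, df = NULL, p = NA_real_, tukey = NULL,
                degenerate = TRUE))
  }
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  th <- stats::TukeyHSD(fit)$groups
  tukey <- data.table::data.table(comparison = rownames(th),
                                  diff = th[, "diff"],
                                  p_adj = th[, "p adj"])
  list(F = s[["F value"]][1], df = s[["Df"]], p = s[["Pr(>F)"]][1],
       tukey = tukey, degenerate = FALSE)
}

#' Trend of sleep gain across the protocol
#'
#' Ordinary least-squares regression of per-episode cohort mean sleep gain
#' on episode index, with the two-sided test of zero slope. A flat response
#' (constant protocol-long gain) indicates flies fully recover within each
#' rebound window rather than accumulating debt.
#'
#' @param gains per-episode cohort mean gains (chronological order).
#' @param index episode indices; defaults to `0, 1, ...`.
#' @return A list with `slope`, `intercept`, `p` (`NA` when the fit is
#'   exact and the slope test is undefined).
#' @export
gain_trend <- function(gains, index = seq_along(gains) - 1) {
  if (length(gains) < 3L)
    stop("need >= 3 episodes for a trend", call. = FALSE)
  fit <- stats::lm(gains ~ index)
  # exact fits make the slope test undefined; reported as p = NA below
  cf <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(cf) < 2L || !is.finite(cf[2L, 4L])) NA_real_ else cf[2L, 4L]
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]), p = p)
}
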