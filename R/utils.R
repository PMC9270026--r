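# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

MIN_PER_DAY <- 1440L
SD_MINUTES <- 150L       # 2.5 h mechanical stimulation
REBOUND_MINUTES <- 270L  # 4.5 h recovery opportunity
EPISODE_MINUTES <- SD_MINUTES + REBOUND_MINUTES

#' @import data.table
NULL

# Column contract for per-minute activity tables.
ACTIVITY_COLS <- c("fly_id", "t", "zt", "count")

check_activity_table <- function(table, require_gapless = TRUE) {
  if (!is.data.frame(table))
    stop("activity table must be a data.frame/data.table", call. = FALSE)
  missing_cols <- setdiff(ACTIVITY_COLS, names(table))
  if (length(missing_cols))
    stop("activity table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dt <- data.table::as.data.table(table)
  if (require_gapless) {
    gaps <- dt[, .(ok = all(diff(t) == 1L)), by = fly_id][!(ok)]
    if (nrow(gaps))
      stop("integrity error: gapped minute grid for fly ",
           paste(gaps$fly_id, collapse = ", "), call. = FALSE)
  }
  invisible(dt)
}

check_sleep_series <- function(series, require_gapless = TRUE) {
  if (!is.data.frame(series))
    stop("sleep series must be a data.frame/data.table", call. = FALSE)
  missing_cols <- setdiff(c("fly_id", "t", "asleep"), names(series))
  if (length(missing_cols))
    stop("sleep series is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dt <- data.table::as.data.table(series)
  if (require_gapless) {
    gaps <- dt[, .(ok = all(diff(t) == 1L)), by = fly_id][!(ok)]
    if (nrow(gaps))
      stop("integrity error: gapped minute grid for fly ",
           paste(gaps$fly_id, collapse = ", "), call. = FALSE)
  }
  invisible(dt)
}

# "HH:MM:SS" (or "HH:MM") -> minutes since midnight
clock_to_minutes <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (!length(parts) %in% 2:3 || anyNA(suppressWarnings(as.numeric(parts))))
    stop("clock time must be 'HH:MM' or 'HH:MM:SS', got: ", x, call. = FALSE)
  as.integer(parts[1]) * 60L + as.integer(parts[2])
}

# Minute-of-day offsets covered by a clock window [zt_a, zt_b) in hours,
# wrapped circularly onto one 24 h day.
clock_window_offsets <- function(window) {
  a <- round(window[1] * 60)
  b <- round(window[2] * 60)
  len <- b - a
  if (len < 0 || len > MIN_PER_DAY)
    stop("clock window must span between 0 and 24 hours", call. = FALSE)
  if (len == 0) return(integer(0))
  as.integer((a + seq_len(len) - 1L) %% MIN_PER_DAY)
}

# Cast a sleep series to a minutes x flies logical matrix on a common grid.
sleep_matrix <- function(series) {
  dt <- check_sleep_series(series)
  data.table::setkey(dt, fly_id, t)
  flies <- unique(dt$fly_id)
  t0 <- min(dt$t)
  n <- max(dt$t) - t0 + 1L
  if (nrow(dt) != n * length(flies))
    stop("integrity error: flies do not share a common gapless grid", call. = FALSE)
  m <- matrix(dt$asleep, nrow = n, ncol = length(flies))
  colnames(m) <- flies
  attr(m, "t0") <- t0
  m
}
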