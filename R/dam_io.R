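#' Read a Trikinetics DAM monitor file
#'
#' Parses a tab-delimited DAM monitor file (one record per minute, 32 count
#' channels per monitor) into a long per-fly, per-minute activity table.
#' Each record carries 10 metadata columns (reading index, date as
#' `"d MMM yy"`, time `"HH:MM:SS"`, a status code, five device fields and a
#' light flag) followed by 32 beam-crossing counts.
#'
#' Zeitgeber time is assigned from the configured lights-on clock time:
#' ZT0 is lights-on and the minute starting at ZT1.5 has `zt = 1.5`. Under
#' constant darkness (`mode = "DD"`) the same mapping is kept and read as
#' circadian time assuming a 24.0 h free-running period.
#'
#' Records whose status differs from `valid_status` are dropped and counted
#' in the `"dropped_records"` attribute of the result; the holes they leave
#' are reported by [validate_dam()] rather than silently filled. Raw records
#' themselves must be contiguous at 1-minute spacing.
#'
#' @param path path to a DAM monitor text file.
#' @param lights_on clock time of lights-on (`"HH:MM:SS"`), defining ZT0.
#' @param mode `"LD"` (12:12 light:dark) or `"DD"` (constant darkness).
#' @param channels integer channels (1-32) to keep.
#' @param fly_ids optional character ids for the kept channels; defaults to
#'   `<monitor>|c<channel>` built from the file name.
#' @param valid_status integer status code accepted as a valid reading.
#' @return A `data.table` with columns `fly_id`, `t` (0-based minutes since
#'   the first record), `zt` (hours in `[0, 24)`) and `count`, keyed by
#'   fly and minute, with attributes `dropped_records` and `lights_on`.
#' @seealso [write_dam()], [validate_dam()]
#' @export
read_dam <- function(path, lights_on = "08:00:00", mode = c("LD", "DD"),
                     channels = 1:32, fly_ids = NULL, valid_status = 1L) {
  mode <- match.arg(mode)
  if (!file.exists(path))
    stop("DAM file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop("DAM file has no records: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths > 42L))
    stop("DAM dialect error: line ", which(widths > 42L)[1],
         " has more than 32 count columns", call. = FALSE)
  if (any(widths != 42L))
    stop("malformed DAM row at line ", which(widths != 42L)[1], ": ",
         widths[widths != 42L][1], " fields (expected 42)", call. = FALSE)
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 42L, byrow = TRUE)

  abs_min <- dam_datetime_minutes(m[, 2L], m[, 3L])
  steps <- diff(abs_min)
  if (any(steps <= 0))
    stop("integrity error: non-monotone timestamps at line ",
         which(steps <= 0)[1] + 1L, call. = FALSE)
  if (any(steps != 1))
    stop("integrity error: records are not 1 minute apart at line ",
         which(steps != 1)[1] + 1L, call. = FALSE)

  status <- as.integer(m[, 4L])
  keep <- status == valid_status
  n_dropped <- sum(!keep)

  if (!all(channels %in% 1:32))
    stop("channels must be within 1..32", call. = FALSE)
  monitor <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(fly_ids))
    fly_ids <- sprintf("%s|c%02d", monitor, channels)
  if (length(fly_ids) != length(channels))
    stop("fly_ids must match channels in length", call. = FALSE)

  counts <- matrix(as.integer(m[, 10L + channels, drop = FALSE]),
                   ncol = length(channels))
  t <- as.integer(abs_min - abs_min[1])
  lo <- clock_to_minutes(lights_on)
  zt <- ((abs_min %% MIN_PER_DAY) - lo) %% MIN_PER_DAY / 60

  out <- data.table::data.table(
    fly_id = rep(fly_ids, each = sum(keep)),
    t = rep(t[keep], times = length(channels)),
    zt = rep(zt[keep], times = length(channels)),
    count = as.vector(counts[keep, , drop = FALSE])
  )
  data.table::setkey(out, fly_id, t)
  data.table::setattr(out, "dropped_records", n_dropped)
  data.table::setattr(out, "lights_on", lights_on)
  data.table::setattr(out, "light_mode", mode)
  out[]
}

#' Write an activity table as a Trikinetics DAM monitor file
#'
#' Emits the standard tab-delimited monitor layout (10 metadata columns plus
#' 32 count columns, UTF-8, LF line endings). Flies are assigned to channels
#' in order of first appearance; unused channels are written as zero counts.
#' Output is byte-stable for identical input and round-trips losslessly
#' through [read_dam()].
#'
#' @param table an activity table (see [read_dam()]); all flies must share
#'   the same gapless minute grid and `zt` must sit on minute resolution.
#' @param path output file path.
#' @param lights_on clock time corresponding to ZT0, used to place records
#'   on the wall clock.
#' @param mode `"LD"` or `"DD"`; controls the written light flag.
#' @param start_date calendar date of the first record.
#' @return `path`, invisibly.
#' @export
write_dam <- function(table, path, lights_on = "08:00:00", mode = c("LD", "DD"),
                      start_date = "2024-01-01") {
  mode <- match.arg(mode)
  dt <- check_activity_table(table)
  flies <- unique(dt$fly_id)
  if (!length(flies))
    stop("cannot write an empty cohort: no flies in table", call. = FALSE)
  if (length(flies) > 32L)
    stop("capacity error: a DAM monitor holds at most 32 flies, got ",
         length(flies), call. = FALSE)
  data.table::setkey(dt, fly_id, t)
  tg <- sort(unique(dt$t))
  if (nrow(dt) != length(tg) * length(flies) || any(diff(tg) != 1L))
    stop("all flies must share the same gapless minute grid", call. = FALSE)
  if (any(dt$count < 0))
    stop("counts must be non-negative", call. = FALSE)

  first <- dt[fly_id == flies[1]]
  zt_min <- round(first$zt * 60)
  if (max(abs(first$zt * 60 - zt_min)) > 1e-6)
    stop("zt must be on a 1-minute grid", call. = FALSE)

  lo <- clock_to_minutes(lights_on)
  day0 <- as.Date(start_date)
  clock0 <- (lo + zt_min[1]) %% MIN_PER_DAY
  abs_min <- clock0 + (first$t - first$t[1])
  date <- day0 + abs_min %/% MIN_PER_DAY
  tod <- abs_min %% MIN_PER_DAY
  time_str <- sprintf("%02d:%02d:00", tod %/% 60L, tod %% 60L)
  date_str <- dam_format_date(date)

  n <- length(tg)
  counts <- matrix(0L, nrow = n, ncol = 32L)
  for (j in seq_along(flies))
    counts[, j] <- dt[fly_id == flies[j]]$count
  light <- if (mode == "LD") as.integer(first$zt < 12) else rep(0L, n)

  meta <- cbind(seq_len(n), date_str, time_str, 1L, 1L, 0L, 0L, 0L, 0L, light)
  body <- cbind(meta, counts)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con, sep = "\n")
  invisible(path)
}

#' Validate an activity table
#'
#' Reports, per fly, missing minutes (grid gaps), negative counts and
#' out-of-range zeitgeber times without modifying the table.
#'
#' @param table an activity table.
#' @return A list with `violations` (a `data.table` with columns `fly_id`,
#'   `type`, `detail`) and `n_violations`.
#' @export
validate_dam <- function(table) {
  dt <- check_activity_table(table, require_gapless = FALSE)
  v <- list()
  gaps <- dt[, .(n_gaps = sum(diff(t) != 1L)), by = fly_id][n_gaps > 0L]
  if (nrow(gaps))
    v <- c(v, list(gaps[, .(fly_id, type = "gap",
                            detail = sprintf("%d missing-minute gap(s)", n_gaps))]))
  neg <- dt[count < 0, .(n = .N), by = fly_id]
  if (nrow(neg))
    v <- c(v, list(neg[, .(fly_id, type = "negative_count",
                           detail = sprintf("%d negative count(s)", n))]))
  ztr <- dt[zt < 0 | zt >= 24, .(n = .N), by = fly_id]
  if (nrow(ztr))
    v <- c(v, list(ztr[, .(fly_id, type = "zt_range",
                           detail = sprintf("%d zt value(s) outside [0, 24)", n))]))
  violations <- if (length(v)) data.table::rbindlist(v) else
    data.table::data.table(fly_id = character(0), type = character(0),
                           detail = character(0))
  list(violations = violations, n_violations = nrow(violations))
}

# --- DAM date handling (locale-independent) ---------------------------------

# "1 Jan 24" / "01 Jan 24" -> absolute minutes, combined with "HH:MM:SS"
dam_datetime_minutes <- function(date_str, time_str) {
  dp <- strsplit(trimws(date_str), " +")
  ok <- lengths(dp) == 3L
  if (any(!ok))
    stop("malformed DAM date at line ", which(!ok)[1], call. = FALSE)
  dpm <- matrix(unlist(dp), ncol = 3L, byrow = TRUE)
  mon <- match(dpm[, 2L], month.abb)
  if (anyNA(mon))
    stop("malformed DAM month at line ", which(is.na(mon))[1], call. = FALSE)
  dates <- as.Date(sprintf("%04d-%02d-%02d", 2000L + as.integer(dpm[, 3L]),
                           mon, as.integer(dpm[, 1L])))
  tp <- strsplit(time_str, ":", fixed = TRUE)
  if (any(lengths(tp) != 3L))
    stop("malformed DAM time at line ", which(lengths(tp) != 3L)[1], call. = FALSE)
  tpm <- matrix(as.integer(unlist(tp)), ncol = 3L, byrow = TRUE)
  as.numeric(dates) * MIN_PER_DAY + tpm[, 1L] * 60 + tpm[, 2L]
}

dam_format_date <- function(date) {
  lt <- as.POSIXlt(date)
  sprintf("%d %s %02d", lt$mday, month.abb[lt$mon + 1L], lt$year %% 100L)
}
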