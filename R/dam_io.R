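#' Light/dark schedule
#'
#' Describes the entrainment regime in Zeitgeber time (ZT): ZT00 is lights-on,
#' and in a 12:12 cycle lights go off at ZT12. An optional temperature profile
#' can be attached for record-keeping; it plays no computational role.
#'
#' @param lights_on Clock time of lights-on, `"HH:MM"` or `"HH:MM:SS"`.
#' @param photophase_hours Hours of light per day (default 12).
#' @param scotophase_hours Hours of dark per day (default `24 - photophase_hours`).
#' @param temperature_profile Optional data.frame with columns `zt_hour`, `temp_c`.
#'
#' @return An object of class `light_schedule`.
#' @export
#'
#' @examples
#' light_schedule("08:00")
light_schedule <- function(lights_on = "08:00:00", photophase_hours = 12,
                           scotophase_hours = 24 - photophase_hours,
                           temperature_profile = NULL) {
  stopifnot(photophase_hours + scotophase_hours == 24,
            photophase_hours > 0, scotophase_hours > 0)
  parts <- as.integer(strsplit(lights_on, ":", fixed = TRUE)[[1]])
  if (length(parts) == 2L) parts <- c(parts, 0L)
  if (length(parts) != 3L || anyNA(parts) || parts[1] > 23 || parts[2] > 59)
    stop("lights_on must be 'HH:MM' or 'HH:MM:SS'")
  structure(list(
    lights_on = sprintf("%02d:%02d:%02d", parts[1], parts[2], parts[3]),
    lights_on_minute = parts[1] * 60L + parts[2],
    photophase_hours = photophase_hours,
    scotophase_hours = scotophase_hours,
    temperature_profile = temperature_profile
  ), class = "light_schedule")
}

#' Per-fly beam-cross series
#'
#' One fly's per-minute infrared beam-cross counts, aligned to a light
#' schedule. Counts must be non-negative integers, one per minute, starting at
#' `start` (a naive local timestamp; timezones and DST are deliberately
#' ignored).
#'
#' @param counts Integer vector of per-minute beam crosses.
#' @param start POSIXct (or parseable string) timestamp of the first minute.
#' @param schedule A [light_schedule()].
#' @param fly_id,line_id,population_id Identifiers.
#' @param latitude Collection latitude in decimal degrees North.
#'
#' @return An object of class `beam_series`.
#' @export
beam_series <- function(counts, start, schedule, fly_id,
                        line_id = NA_character_, population_id = NA_character_,
                        latitude = NA_real_) {
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (!inherits(schedule, "light_schedule")) stop("schedule must be a light_schedule")
  if (!inherits(start, "POSIXct")) start <- as.POSIXct(start, tz = "UTC")
  structure(list(
    fly_id = as.character(fly_id), line_id = as.character(line_id),
    population_id = as.character(population_id), latitude = latitude,
    start = start, counts = as.integer(counts), schedule = schedule,
    gaps = integer(0)
  ), class = "beam_series")
}

#' @export
print.beam_series <- function(x, ...) {
  cat(sprintf("<beam_series> fly %s (line %s, pop %s, %.1f°N): %d min from %s\n",
              x$fly_id, x$line_id, x$population_id, x$latitude,
              length(x$counts), format(x$start)))
  invisible(x)
}

#' @export
length.beam_series <- function(x) length(x$counts)

#' Zeitgeber time of each minute
#'
#' @param series A [beam_series()].
#' @return Integer vector, same length as the series: minutes since lights-on
#'   modulo 1440 (ZT00 = 0, ZT12 = 720).
#' @export
zt_minutes <- function(series) {
  start_min <- as.integer(format(series$start, "%H")) * 60L +
    as.integer(format(series$start, "%M"))
  (start_min - series$schedule$lights_on_minute +
      seq_along(series$counts) - 1L) %% 1440L
}

#' Photophase/scotophase label of each minute
#'
#' @param series A [beam_series()].
#' @return Character vector `"photophase"`/`"scotophase"` per minute.
#' @export
phase_labels <- function(series) {
  zt <- zt_minutes(series)
  ifelse(zt < series$schedule$photophase_hours * 60L, "photophase", "scotophase")
}

#' Trikinetics DAM file column layout
#'
#' The common 42-column monitor-file dialect: reading index, date, time, a
#' status code, six metadata columns, then 32 channel counts. Indices are
#' configurable for other dialects.
#'
#' @param n_columns Total tab-separated columns per row.
#' @param status_col Column holding the status code.
#' @param channel_cols Columns holding the 32 channel counts.
#' @param ok_status Status value meaning a valid reading.
#' @export
dam_layout <- function(n_columns = 42L, status_col = 4L,
                       channel_cols = 11:42, ok_status = 1L) {
  stopifnot(max(channel_cols) <= n_columns, status_col <= n_columns)
  structure(list(n_columns = as.integer(n_columns),
                 status_col = as.integer(status_col),
                 channel_cols = as.integer(channel_cols),
                 ok_status = as.integer(ok_status)),
            class = "dam_layout")
}

#' Sample sheet constructor
#'
#' Maps (monitor, channel) to fly, isofemale line, population and latitude.
#'
#' @param monitor,channel,fly_id,line_id,population_id,latitude Equal-length vectors.
#' @return A data.frame; (monitor, channel) pairs must be unique.
#' @export
sample_sheet <- function(monitor, channel, fly_id, line_id, population_id, latitude) {
  df <- data.frame(monitor = as.character(monitor), channel = as.integer(channel),
                   fly_id = as.character(fly_id), line_id = as.character(line_id),
                   population_id = as.character(population_id),
                   latitude = as.numeric(latitude), stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("monitor", "channel")]))
    stop("duplicate (monitor, channel) in sample sheet")
  if (any(!is.finite(df$latitude))) stop("latitude must be finite")
  df
}

.parse_dam_timestamp <- function(date, time) {
  old <- Sys.getlocale("LC_TIME"); on.exit(Sys.setlocale("LC_TIME", old))
  suppressWarnings(Sys.setlocale("LC_TIME", "C"))
  ts <- as.POSIXct(paste(date, time), format = "%d %b %y %H:%M:%S", tz = "UTC")
  bad <- is.na(ts)
  if (any(bad)) {  # ISO fallback
    ts[bad] <- as.POSIXct(paste(date[bad], time[bad]),
                          format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  ts
}

#' Read a Trikinetics-style DAM monitor file
#'
#' Parses a tab-delimited monitor file (one row per 1-min reading) into one
#' [beam_series()] per channel mapped in the sample sheet. Rows whose status
#' code differs from the layout's OK value are treated as gaps; under the
#' default `"zero_fill"` policy the affected minutes get count 0 and their
#' indices are recorded in the series' `gaps` field, while `"drop_day"`
#' additionally zero-fills every minute of each ZT day containing a gap and
#' records the whole day. Unmapped channels are skipped with a warning.
#'
#' @param path Monitor file path.
#' @param samplesheet A [sample_sheet()].
#' @param schedule A [light_schedule()].
#' @param monitor Monitor name to select from the sheet; defaults to the single
#'   monitor present.
#' @param layout A [dam_layout()].
#' @param gap_policy `"zero_fill"` (default) or `"drop_day"`.
#'
#' @return List of `beam_series`, one per mapped channel.
#' @export
read_dam_monitor_file <- function(path, samplesheet, schedule, monitor = NULL,
                                  layout = dam_layout(),
                                  gap_policy = c("zero_fill", "drop_day")) {
  gap_policy <- match.arg(gap_policy)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty DAM file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != layout$n_columns))
    stop(sprintf("malformed row at line %d: %d fields, expected %d",
                 which(nf != layout$n_columns)[1],
                 nf[which(nf != layout$n_columns)[1]], layout$n_columns))
  mat <- do.call(rbind, fields)
  ts <- .parse_dam_timestamp(mat[, 2], mat[, 3])
  if (anyNA(ts)) stop("unparseable timestamp at line ", which(is.na(ts))[1])
  if (any(diff(as.numeric(ts)) <= 0)) stop("non-monotone timestamps in ", path)
  status <- suppressWarnings(as.integer(mat[, layout$status_col]))
  gap_rows <- which(is.na(status) | status != layout$ok_status)

  if (is.null(monitor)) {
    mons <- unique(samplesheet$monitor)
    if (length(mons) != 1L)
      stop("sample sheet lists several monitors; supply `monitor`")
    monitor <- mons
  }
  sheet <- samplesheet[samplesheet$monitor == monitor, , drop = FALSE]
  n_chan <- length(layout$channel_cols)
  if (any(sheet$channel > n_chan)) {
    warning("sample sheet channels beyond file layout skipped")
    sheet <- sheet[sheet$channel <= n_chan, , drop = FALSE]
  }
  unmapped <- setdiff(seq_len(n_chan), sheet$channel)
  if (length(unmapped)) {
    act <- vapply(unmapped, function(ch) {
      any(suppressWarnings(as.integer(mat[, layout$channel_cols[ch]])) > 0, na.rm = TRUE)
    }, logical(1))
    if (any(act))
      warning("unmapped channel(s) with activity skipped: ",
              paste(unmapped[act], collapse = ", "))
  }

  out <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    col <- layout$channel_cols[sheet$channel[i]]
    counts <- suppressWarnings(as.integer(mat[, col]))
    if (anyNA(counts[-gap_rows]))
      stop("non-integer count in channel ", sheet$channel[i])
    counts[gap_rows] <- 0L
    s <- beam_series(counts, ts[1], schedule, sheet$fly_id[i],
                     sheet$line_id[i], sheet$population_id[i], sheet$latitude[i])
    gaps <- gap_rows
    if (gap_policy == "drop_day" && length(gap_rows)) {
      day <- (seq_along(counts) - 1L + zt_minutes(s)[1]) %/% 1440L
      bad_days <- unique(day[gap_rows])
      gaps <- which(day %in% bad_days)
      s$counts[gaps] <- 0L
    }
    s$gaps <- gaps
    out[[i]] <- s
  }
  names(out) <- sheet$fly_id
  out
}

#' Write beam-cross series as a DAM monitor file
#'
#' Inverse of [read_dam_monitor_file()] for series sharing a common start and
#' length: channel `i` receives the counts of `series_list[[i]]`, remaining
#' channels are zero. Round-trips counts exactly.
#'
#' @param series_list List of `beam_series` (at most 32).
#' @param path Output path.
#' @param layout A [dam_layout()].
#' @export
write_dam_monitor_file <- function(series_list, path, layout = dam_layout()) {
  stopifnot(length(series_list) >= 1, length(series_list) <= length(layout$channel_cols))
  n <- length(series_list[[1]]$counts)
  if (!all(vapply(series_list, function(s) length(s$counts) == n, logical(1))))
    stop("all series must have equal length")
  start <- series_list[[1]]$start
  ts <- start + 60 * (seq_len(n) - 1)
  old <- Sys.getlocale("LC_TIME"); on.exit(Sys.setlocale("LC_TIME", old))
  suppressWarnings(Sys.setlocale("LC_TIME", "C"))
  mat <- matrix("0", nrow = n, ncol = layout$n_columns)
  mat[, 1] <- as.character(seq_len(n))
  mat[, 2] <- format(ts, "%d %b %y")
  mat[, 3] <- format(ts, "%H:%M:%S")
  mat[, layout$status_col] <- as.character(layout$ok_status)
  for (i in seq_along(series_list))
    mat[, layout$channel_cols[i]] <- as.character(series_list[[i]]$counts)
  writeLines(apply(mat, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read long-format activity CSV
#'
#' Alternative input dialect: columns `fly_id`, `timestamp`, `count`, with
#' optional `line_id`, `population_id`, `latitude`.
#'
#' @param path CSV path.
#' @param schedule A [light_schedule()].
#' @return List of `beam_series`, one per fly.
#' @export
read_activity_csv <- function(path, schedule) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("fly_id", "timestamp", "count")
  if (!all(req %in% names(df))) stop("need columns: ", paste(req, collapse = ", "))
  lapply(split(df, df$fly_id), function(d) {
    d <- d[order(d$timestamp), ]
    ts <- as.POSIXct(d$timestamp, tz = "UTC")
    if (any(diff(as.numeric(ts)) != 60)) stop("minutes not contiguous for fly ", d$fly_id[1])
    beam_series(d$count, ts[1], schedule, d$fly_id[1],
                if ("line_id" %in% names(d)) d$line_id[1] else NA,
                if ("population_id" %in% names(d)) d$population_id[1] else NA,
                if ("latitude" %in% names(d)) d$latitude[1] else NA_real_)
  })
}

#' Restrict a series to a span of experiment days
#'
#' A "day" runs ZT00 to ZT24 (lights-on to lights-on); day 1 is the first full
#' ZT-aligned day of the recording. The standard analysis window keeps days 5
#' through 12, discarding the acclimation period.
#'
#' @param series A [beam_series()].
#' @param first_day,last_day 1-based day numbers, inclusive.
#' @return A `beam_series` of exactly `(last_day - first_day + 1) * 1440`
#'   minutes, starting at ZT00.
#' @export
slice_experiment_days <- function(series, first_day, last_day) {
  stopifnot(first_day >= 1, last_day >= first_day)
  zt <- zt_minutes(series)
  offset <- (1440L - zt[1]) %% 1440L   # minutes until first ZT00
  need <- offset + last_day * 1440L
  if (length(series$counts) < need) {
    avail <- (length(series$counts) - offset) %/% 1440L
    stop(sprintf("series covers only %d full ZT day(s); need day %d", avail, last_day))
  }
  from <- offset + (first_day - 1L) * 1440L + 1L
  to <- offset + last_day * 1440L
  out <- series
  out$counts <- series$counts[from:to]
  out$start <- series$start + 60 * (from - 1)
  out$gaps <- series$gaps[series$gaps >= from & series$gaps <= to] - (from - 1L)
  out
}

#' Write a tidy phenotype table
#'
#' Serialises line- or population-level summaries as CSV, one row per
#' (unit, phase, metric).
#'
#' @param summaries A data.frame as produced by [aggregate_phenotypes()].
#' @param path Output CSV path.
#' @export
write_phenotype_table <- function(summaries, path) {
  stopifnot(is.data.frame(summaries))
  utils::write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}
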