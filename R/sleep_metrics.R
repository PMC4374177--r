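#' Detect sleep bouts
#'
#' A sleep bout is a maximal run of at least `threshold` consecutive minutes
#' with zero beam crosses — the field-standard operational definition of
#' Drosophila sleep (threshold 5). Runs touching the series boundaries are
#' counted from/to the boundary.
#'
#' @param series A [beam_series()], or a bare count vector (then `phase_at_start`
#'   is computed assuming the first minute is ZT00 under a 12:12 schedule).
#' @param threshold Minimum bout length in minutes (default 5).
#'
#' @return data.frame with columns `start_minute` (1-based index), `duration`
#'   (minutes) and `phase_at_start` (`"photophase"`/`"scotophase"`).
#' @export
#'
#' @examples
#' detect_sleep_bouts(c(1, 0, 0, 0, 0, 0, 2))  # one 5-min bout starting at minute 2
detect_sleep_bouts <- function(series, threshold = 5L) {
  if (inherits(series, "beam_series")) {
    counts <- series$counts
    phase <- phase_labels(series)
  } else {
    counts <- series
    phase <- rep_len(c(rep("photophase", 720L), rep("scotophase", 720L)),
                     length(counts))
  }
  r <- rle(counts == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= threshold
  data.frame(start_minute = starts[keep], duration = r$lengths[keep],
             phase_at_start = phase[starts[keep]], stringsAsFactors = FALSE)
}

.rolling_sums <- function(counts, window) {
  cs <- cumsum(c(0, counts))
  cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]
}

#' Exclude non-informative individuals
#'
#' A fly is discarded when any 24 consecutive hours of its record contain 24
#' or fewer beam crosses (dead or inert animals). All 1440-minute sliding
#' windows are examined, not just ZT-aligned days.
#'
#' @param series_list List of [beam_series()], sliced to the analysis days.
#' @param max_crosses Discard threshold: window sum `<= max_crosses` (default 24).
#' @param window_minutes Window length (default 1440).
#'
#' @return List with `kept` (list of series) and `discarded` (data.frame of
#'   `fly_id`, `window_start`, `window_sum` for the first triggering window).
#' @export
filter_individuals <- function(series_list, max_crosses = 24L, window_minutes = 1440L) {
  stopifnot(length(series_list) > 0)
  disc <- list()
  keep <- logical(length(series_list))
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    if (length(s$counts) < window_minutes)
      stop("series for fly ", s$fly_id, " shorter than ", window_minutes, " minutes")
    sums <- .rolling_sums(s$counts, window_minutes)
    j <- which(sums <= max_crosses)
    if (length(j)) {
      disc[[length(disc) + 1L]] <- data.frame(
        fly_id = s$fly_id, window_start = j[1], window_sum = sums[j[1]],
        stringsAsFactors = FALSE)
    } else keep[i] <- TRUE
  }
  discarded <- if (length(disc)) do.call(rbind, disc) else
    data.frame(fly_id = character(), window_start = integer(), window_sum = numeric())
  list(kept = series_list[keep], discarded = discarded)
}

.phase_idx <- function(series, phase) phase_labels(series) == phase

#' Locomotor activity (beam crosses per minute)
#'
#' Total crosses during the given phase divided by the number of phase
#' minutes, i.e. the per-minute rate averaged across days.
#'
#' @param series A [beam_series()].
#' @param phase `"photophase"` or `"scotophase"`.
#' @return Crosses per minute.
#' @export
compute_locomotor_activity <- function(series, phase = c("photophase", "scotophase")) {
  phase <- match.arg(phase)
  idx <- .phase_idx(series, phase)
  if (!any(idx)) return(NA_real_)
  sum(series$counts[idx]) / sum(idx)
}

#' Walking speed (beam crosses per active minute)
#'
#' Crosses per unit time excluding inactive time: total phase crosses divided
#' by the number of phase minutes with at least one cross. Undefined (NA) when
#' the fly never moves during the phase; such values are dropped from
#' aggregation.
#'
#' @inheritParams compute_locomotor_activity
#' @return Crosses per active minute, or NA.
#' @export
compute_walking_speed <- function(series, phase = c("photophase", "scotophase")) {
  phase <- match.arg(phase)
  idx <- .phase_idx(series, phase)
  active <- idx & series$counts > 0L
  if (!any(active)) return(NA_real_)
  sum(series$counts[idx]) / sum(active)
}

#' Per-phase sleep variables
#'
#' Computes daily sleep duration, sleep bout number and average sleep bout
#' duration for one phase. Bouts spanning the phase boundary are handled by
#' the attribution policy: under `"split"` (default) the bout's minutes are
#' divided between the phases for `sleep_duration`, while the bout itself —
#' and its full duration — is attributed to its starting phase for
#' `bout_number` and `avg_bout_duration`; under `"start"` all minutes follow
#' the starting phase too. `avg_over = "bouts"` averages over all bouts of the
#' phase; `"days"` first averages within days, then across days.
#'
#' @param series A [beam_series()] (whole analysis window).
#' @param phase `"photophase"` or `"scotophase"`.
#' @param threshold Minimum bout length (default 5).
#' @param attribution `"split"` or `"start"`.
#' @param avg_over `"bouts"` or `"days"`.
#'
#' @return list(sleep_duration = minutes/day, bout_number = bouts/day,
#'   avg_bout_duration = minutes; NA when no bout starts in the phase).
#' @export
compute_sleep_variables <- function(series, phase = c("photophase", "scotophase"),
                                    threshold = 5L,
                                    attribution = c("split", "start"),
                                    avg_over = c("bouts", "days")) {
  phase <- match.arg(phase)
  attribution <- match.arg(attribution)
  avg_over <- match.arg(avg_over)
  n_days <- length(series$counts) / 1440
  bouts <- detect_sleep_bouts(series, threshold)
  ph <- phase_labels(series)
  in_phase <- ph == phase

  if (nrow(bouts) == 0L)
    return(list(sleep_duration = 0, bout_number = 0, avg_bout_duration = NA_real_))

  if (attribution == "split") {
    sleep_min <- sum(vapply(seq_len(nrow(bouts)), function(i) {
      sum(in_phase[bouts$start_minute[i]:(bouts$start_minute[i] + bouts$duration[i] - 1L)])
    }, numeric(1)))
  } else {
    sleep_min <- sum(bouts$duration[bouts$phase_at_start == phase])
  }

  own <- bouts[bouts$phase_at_start == phase, , drop = FALSE]
  avg_dur <- if (nrow(own) == 0L) NA_real_ else if (avg_over == "bouts") {
    mean(own$duration)
  } else {
    day <- (own$start_minute - 1L) %/% 1440L
    mean(tapply(own$duration, day, mean))
  }
  list(sleep_duration = sleep_min / n_days,
       bout_number = nrow(own) / n_days,
       avg_bout_duration = avg_dur)
}

#' Hourly average sleep bout duration
#'
#' Mean duration of sleep bouts grouped by the ZT hour of their starting
#' minute; hours with no bout get NA.
#'
#' @inheritParams compute_sleep_variables
#' @return Numeric vector of length 24, named ZT00..ZT23.
#' @export
hourly_bout_duration <- function(series, threshold = 5L) {
  bouts <- detect_sleep_bouts(series, threshold)
  out <- rep(NA_real_, 24L)
  names(out) <- sprintf("ZT%02d", 0:23)
  if (nrow(bouts)) {
    zt_h <- zt_minutes(series)[bouts$start_minute] %/% 60L
    m <- tapply(bouts$duration, factor(zt_h, levels = 0:23), mean)
    out[] <- as.numeric(m)
  }
  out
}

#' All phenotypes for one fly
#'
#' @inheritParams compute_sleep_variables
#' @return data.frame with two rows (photophase, scotophase) and columns
#'   fly_id, line_id, population_id, latitude, phase, locomotor_activity,
#'   walking_speed, sleep_duration, sleep_bout_number, avg_sleep_bout_duration.
#'   The 24-vector of hourly bout durations is attached as attribute `hourly`.
#' @export
fly_phenotype <- function(series, threshold = 5L,
                          attribution = c("split", "start"),
                          avg_over = c("bouts", "days")) {
  attribution <- match.arg(attribution); avg_over <- match.arg(avg_over)
  rows <- lapply(c("photophase", "scotophase"), function(ph) {
    sv <- compute_sleep_variables(series, ph, threshold, attribution, avg_over)
    data.frame(fly_id = series$fly_id, line_id = series$line_id,
               population_id = series$population_id, latitude = series$latitude,
               phase = ph,
               locomotor_activity = compute_locomotor_activity(series, ph),
               walking_speed = compute_walking_speed(series, ph),
               sleep_duration = sv$sleep_duration,
               sleep_bout_number = sv$bout_number,
               avg_sleep_bout_duration = sv$avg_bout_duration,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "hourly") <- hourly_bout_duration(series, threshold)
  out
}

.metric_cols <- c("locomotor_activity", "walking_speed", "sleep_duration",
                  "sleep_bout_number", "avg_sleep_bout_duration")

#' Two-stage phenotype aggregation
#'
#' Strict unweighted averaging up the fly -> isofemale line -> population
#' hierarchy: a line's value is the mean over its flies, a population's value
#' the mean over its lines (never the pooled-fly mean), and the s.e.m. is the
#' standard deviation of line means divided by sqrt(n_lines). Missing fly
#' values (e.g. undefined walking speed) are dropped at each stage.
#'
#' @param fly_df Row-bound [fly_phenotype()] tables.
#' @return list(line = line-level data.frame, population = population-level
#'   data.frame with `<metric>_sem` columns and `n_lines`).
#' @export
aggregate_phenotypes <- function(fly_df) {
  stopifnot(all(c("line_id", "population_id", "phase") %in% names(fly_df)))
  met <- intersect(.metric_cols, names(fly_df))
  line <- stats::aggregate(fly_df[met],
                           by = fly_df[c("population_id", "latitude", "line_id", "phase")],
                           FUN = mean, na.rm = TRUE)
  nfly <- stats::aggregate(list(n_flies = fly_df$fly_id),
                           by = fly_df[c("line_id", "phase")],
                           FUN = function(x) length(unique(x)))
  line <- merge(line, nfly, by = c("line_id", "phase"), sort = FALSE)
  line[met] <- lapply(line[met], function(x) { x[is.nan(x)] <- NA; x })

  pop_mean <- stats::aggregate(line[met],
                               by = line[c("population_id", "latitude", "phase")],
                               FUN = mean, na.rm = TRUE)
  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  pop_sem <- stats::aggregate(line[met],
                              by = line[c("population_id", "latitude", "phase")],
                              FUN = sem)
  names(pop_sem)[match(met, names(pop_sem))] <- paste0(met, "_sem")
  nl <- stats::aggregate(list(n_lines = line$line_id),
                         by = line[c("population_id", "phase")],
                         FUN = function(x) length(unique(x)))
  pop <- merge(merge(pop_mean, pop_sem,
                     by = c("population_id", "latitude", "phase"), sort = FALSE),
               nl, by = c("population_id", "phase"), sort = FALSE)
  pop[met] <- lapply(pop[met], function(x) { x[is.nan(x)] <- NA; x })
  list(line = line, population = pop)
}

#' Hourly bout-duration table across flies
#'
#' Builds the per-(population, line, hour) mean bout duration table used by
#' the hour-by-hour cline scan, with the same two-stage averaging as
#' [aggregate_phenotypes()].
#'
#' @param series_list List of [beam_series()].
#' @param threshold Minimum bout length.
#' @return data.frame: population_id, latitude, zt_hour (0..23), value
#'   (population mean of line means of fly hourly bout durations).
#' @export
hourly_population_means <- function(series_list, threshold = 5L) {
  per_fly <- do.call(rbind, lapply(series_list, function(s) {
    h <- hourly_bout_duration(s, threshold)
    data.frame(population_id = s$population_id, latitude = s$latitude,
               line_id = s$line_id, zt_hour = 0:23, value = as.numeric(h),
               stringsAsFactors = FALSE)
  }))
  line <- stats::aggregate(list(value = per_fly$value),
                           by = per_fly[c("population_id", "latitude", "line_id", "zt_hour")],
                           FUN = mean, na.rm = TRUE)
  pop <- stats::aggregate(list(value = line$value),
                          by = line[c("population_id", "latitude", "zt_hour")],
                          FUN = mean, na.rm = TRUE)
  pop$value[is.nan(pop$value)] <- NA
  pop
}
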