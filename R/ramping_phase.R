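#' Pre-dawn ramping profile of one line
#'
#' Quantifies sunrise anticipation: activity in 30-minute ZT bins over the
#' late night (ZT18.0–ZT23.5, 12 bins by default), averaged first across days
#' within each fly, then across flies within the line, and min–max normalised
#' over the binned curve: `(A_t - A_min) / (A_max - A_min)`. A flat curve
#' (`A_max == A_min`) has no defined normalisation; the line is flagged
#' undefined.
#'
#' @param series_list List of [beam_series()] belonging to one line, sliced to
#'   the analysis days.
#' @param bin_minutes Bin width in minutes (default 30).
#' @param zt_start,zt_end Window of interest in ZT hours (default 18 and 24,
#'   i.e. bins starting ZT18.0 ... ZT23.5).
#' @return list(line_id, bin_zt = bin start hours, activity = A_t,
#'   normalized, a_min, a_max, defined).
#' @export
compute_ramping_profile <- function(series_list, bin_minutes = 30L,
                                    zt_start = 18, zt_end = 24) {
  stopifnot(length(series_list) >= 1)
  n_bins <- as.integer((zt_end - zt_start) * 60 / bin_minutes)
  fly_curves <- vapply(series_list, function(s) {
    zt <- zt_minutes(s)
    sel <- zt >= zt_start * 60 & zt < zt_end * 60
    bin <- (zt[sel] - zt_start * 60L) %/% bin_minutes
    day <- (seq_along(s$counts) - 1L) %/% 1440L
    # per-day per-bin sums, then mean across days
    sums <- tapply(s$counts[sel], list(factor(bin, levels = 0:(n_bins - 1)),
                                       day[sel]), sum)
    rowMeans(sums, na.rm = TRUE)
  }, numeric(n_bins))
  a_t <- rowMeans(matrix(fly_curves, nrow = n_bins), na.rm = TRUE)
  a_min <- min(a_t); a_max <- max(a_t)
  defined <- a_max > a_min
  norm <- if (defined) (a_t - a_min) / (a_max - a_min) else rep(NA_real_, n_bins)
  list(line_id = series_list[[1]]$line_id,
       bin_zt = zt_start + (seq_len(n_bins) - 1) * bin_minutes / 60,
       activity = as.numeric(a_t), normalized = as.numeric(norm),
       a_min = a_min, a_max = a_max, defined = defined)
}

#' Population ramping curve
#'
#' Mean of the normalised line curves; undefined lines are dropped with a
#' warning.
#'
#' @param profiles List of [compute_ramping_profile()] outputs for one
#'   population.
#' @return Numeric vector, one value per bin.
#' @export
ramping_population_curve <- function(profiles) {
  ok <- vapply(profiles, `[[`, logical(1), "defined")
  if (!all(ok))
    warning(sum(!ok), " line(s) with flat ramping window excluded")
  if (!any(ok)) stop("no line has a defined ramping profile")
  rowMeans(vapply(profiles[ok], `[[`, numeric(length(profiles[[1]]$normalized)),
                  "normalized"))
}

#' Per-bin latitudinal regression of ramping curves
#'
#' For each late-night bin, ordinary least squares of the population mean
#' normalised activity on latitude, quantifying where in the night the
#' geographic signal of sunrise anticipation lies.
#'
#' @param pop_curves Matrix (populations x bins) of normalised activity, or a
#'   list of per-population curves.
#' @param latitudes Latitude per population (row).
#' @param bin_zt Optional bin start hours for labelling.
#' @return data.frame: bin_zt, r_squared, p_value, slope (NA with zero
#'   variance in the response).
#' @export
ramping_cline_scan <- function(pop_curves, latitudes, bin_zt = NULL) {
  if (is.list(pop_curves)) pop_curves <- do.call(rbind, pop_curves)
  stopifnot(nrow(pop_curves) == length(latitudes))
  if (nrow(pop_curves) < 3)
    warning("fewer than 3 populations: R-squared is uninformative")
  if (is.null(bin_zt)) bin_zt <- seq_len(ncol(pop_curves))
  rows <- lapply(seq_len(ncol(pop_curves)), function(j) {
    y <- pop_curves[, j]
    if (stats::var(y) == 0 || length(y) < 3)
      return(data.frame(bin_zt = bin_zt[j], slope = NA_real_,
                        r_squared = if (stats::var(y) == 0) 0 else NA_real_,
                        p_value = NA_real_))
    fit <- regress_on_latitude(latitudes, y)
    data.frame(bin_zt = bin_zt[j], slope = fit$slope,
               r_squared = fit$r_squared, p_value = fit$p_value)
  })
  do.call(rbind, rows)
}

.moving_average <- function(x, width) {
  if (width <= 1) return(x)
  k <- rep(1 / width, width)
  as.numeric(stats::filter(x, k, sides = 2, circular = TRUE))
}

#' Circadian peak phase under constant darkness
#'
#' Estimates the phase of the morning or evening activity peak from DD data.
#' Counts are smoothed with a centred moving average, folded at the
#' free-running period (estimated by [estimate_period()] unless supplied),
#' and the maximum of the folded mean profile is located within the searched
#' half-cycle (morning: first half of the subjective day; evening: second
#' half). Ties take the earliest bin. The first DD day is skipped as an
#' entrainment transient by default.
#'
#' @param series A [beam_series()] recorded in DD (ZT here means subjective
#'   time from the start of the analysed span).
#' @param component `"morning"` or `"evening"`.
#' @param period Free-running period in hours; NULL to estimate.
#' @param smooth_minutes Moving-average width (default 60).
#' @param skip_days Initial days discarded (default 1).
#' @return Peak phase in hours after subjective lights-on, or NA for a flat
#'   signal.
#' @export
estimate_phase <- function(series, component = c("morning", "evening"),
                           period = NULL, smooth_minutes = 60L, skip_days = 1L) {
  component <- match.arg(component)
  counts <- series$counts
  skip <- as.integer(skip_days * 1440L)
  if (skip > 0) {
    if (length(counts) <= skip) stop("series too short after skip_days")
    counts <- counts[-seq_len(skip)]
  }
  if (all(counts == counts[1])) return(NA_real_)
  if (is.null(period)) {
    period <- estimate_period(beam_series(counts, series$start, series$schedule,
                                          series$fly_id))
    if (is.na(period)) return(NA_real_)
  }
  p_min <- as.integer(round(period * 60))
  if (length(counts) < 2 * p_min) stop("need at least two full cycles")
  sm <- .moving_average(counts, smooth_minutes)
  # fold keeping the ORIGINAL series start as the subjective time origin,
  # so the skipped transient does not shift the phase reference
  fold_idx <- (skip + seq_along(sm) - 1L) %% p_min
  prof <- as.numeric(tapply(sm, factor(fold_idx, levels = 0:(p_min - 1L)),
                            mean, na.rm = TRUE))
  half <- if (component == "morning") seq_len(p_min %/% 2) else
    (p_min %/% 2 + 1L):p_min
  seg <- prof[half]
  if (all(is.na(seg)) || max(seg, na.rm = TRUE) == min(seg, na.rm = TRUE))
    return(NA_real_)
  (half[which.max(seg)] - 1) / 60
}

#' Free-running period by chi-square periodogram
#'
#' Sokolove–Bushell chi-square periodogram over candidate periods 20–28 h in
#' 0.1-h steps: the data are folded at each candidate period P (integer
#' minutes) over K complete cycles, and the statistic
#' Q_P = K * sum_h (M_h - M)^2 / sigma^2 (column means M_h, grand mean M, raw
#' variance sigma^2 of the folded data) is compared with the chi-square
#' quantile at P - 1 degrees of freedom, Bonferroni-corrected across the
#' candidate grid so that arrhythmic noise rarely produces a spurious period.
#' The reported period is the candidate maximising Q_P minus its significance
#' line; if no candidate is significant the estimate is NA.
#'
#' @param series A [beam_series()] in DD.
#' @param range_hours Search range (default c(20, 28)).
#' @param step_hours Grid step (default 0.1).
#' @param alpha Significance level for the chi-square line (default 0.05).
#' @return Period in hours, or NA when no significant periodicity exists.
#' @export
estimate_period <- function(series, range_hours = c(20, 28), step_hours = 0.1,
                            alpha = 0.05) {
  counts <- as.numeric(series$counts)
  periods <- seq(range_hours[1], range_hours[2], by = step_hours)
  if (length(counts) < 2 * max(periods) * 60)
    stop("need at least two full cycles at the longest candidate period")
  m <- mean(counts); v <- mean((counts - m)^2)
  if (v == 0) return(NA_real_)
  q <- vapply(periods, function(ph) {
    p <- as.integer(round(ph * 60))
    k <- length(counts) %/% p
    x <- matrix(counts[seq_len(k * p)], nrow = p)
    bin_means <- rowMeans(x)
    sigma2 <- mean((x - mean(x))^2)
    if (sigma2 == 0) return(0)
    k * sum((bin_means - mean(x))^2) / sigma2
  }, numeric(1))
  crit <- vapply(periods, function(ph) {
    p <- as.integer(round(ph * 60))
    stats::qchisq(1 - alpha / length(periods), df = p - 1)
  }, numeric(1))
  excess <- q - crit
  if (all(excess <= 0)) return(NA_real_)
  periods[which.max(excess)]
}
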