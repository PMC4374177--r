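#' Latitudinal cline regression
#'
#' Ordinary least squares of population phenotypic means on latitude; the
#' populations — not pooled lines or flies — are the regression units. Returns
#' the slope (trait units per degree N), R-squared and the two-sided p-value
#' for the slope from the t distribution with n - 2 df.
#'
#' @param latitude Numeric vector (degrees N), or a two-column
#'   data.frame/matrix of (latitude, value) pairs.
#' @param value Population means (omit when `latitude` holds both columns).
#' @return list(slope, intercept, r_squared, p_value, n).
#' @export
regress_on_latitude <- function(latitude, value = NULL) {
  if (is.null(value)) {
    stopifnot(ncol(latitude) == 2)
    value <- latitude[[2]]; latitude <- latitude[[1]]
  }
  ok <- is.finite(latitude) & is.finite(value)
  latitude <- latitude[ok]; value <- value[ok]
  n <- length(latitude)
  if (n < 3) stop("need at least 3 populations, got ", n)
  if (stats::var(latitude) == 0) stop("zero variance in latitude")
  if (stats::var(value) == 0)  # constant response: flat fit, no slope test
    return(list(slope = 0, intercept = value[1], r_squared = 0,
                p_value = NA_real_, n = n))
  fit <- stats::lm(value ~ latitude)
  sm <- suppressWarnings(summary(fit))  # collinear points: perfect-fit warning
  list(slope = unname(stats::coef(fit)["latitude"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients["latitude", 4], n = n)
}

#' Hour-by-hour cline scan
#'
#' Regresses each ZT hour's population mean (e.g. average sleep bout
#' duration) on latitude — 24 regressions — and applies Bonferroni correction
#' for m = 24 tests.
#'
#' @param hourly_means data.frame with columns `latitude`, `zt_hour` (0–23)
#'   and `value`, one row per (population, hour) (see
#'   [hourly_population_means()]).
#' @param alpha Family-wise level (default 0.05).
#' @return data.frame with one row per hour: zt_hour, slope, r_squared,
#'   p_value, significant_raw, significant_after_correction; attribute
#'   `bonferroni_alpha` = alpha / 24.
#' @export
hourly_cline_scan <- function(hourly_means, alpha = 0.05) {
  stopifnot(all(c("latitude", "zt_hour", "value") %in% names(hourly_means)))
  m <- 24L
  rows <- lapply(0:23, function(h) {
    d <- hourly_means[hourly_means$zt_hour == h & !is.na(hourly_means$value), ]
    if (nrow(d) < 3 || stats::var(d$latitude) == 0)
      return(data.frame(zt_hour = h, slope = NA_real_, r_squared = NA_real_,
                        p_value = NA_real_))
    fit <- regress_on_latitude(d$latitude, d$value)
    data.frame(zt_hour = h, slope = fit$slope, r_squared = fit$r_squared,
               p_value = fit$p_value)
  })
  out <- do.call(rbind, rows)
  out$significant_raw <- !is.na(out$p_value) & out$p_value <= alpha
  out$significant_after_correction <- !is.na(out$p_value) & out$p_value <= alpha / m
  attr(out, "bonferroni_alpha") <- alpha / m
  out
}

#' Nonparametric two-group comparison
#'
#' Two-sided Wilcoxon rank-sum test with mid-rank tie handling (exact when
#' sample sizes permit and there are no ties, normal approximation otherwise);
#' with more than two groups, Kruskal–Wallis. Used because phenotype
#' distributions are typically non-normal even after transformation.
#'
#' @param group_a,group_b Numeric vectors; or `group_a` a list of >2 groups
#'   with `group_b = NULL`.
#' @return Two-sided p-value (NA if either group is empty).
#' @export
nonparametric_compare <- function(group_a, group_b = NULL) {
  if (is.list(group_a) && is.null(group_b)) {
    if (length(group_a) < 2) stop("need at least two groups")
    return(stats::kruskal.test(group_a)$p.value)
  }
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  if (!length(group_a) || !length(group_b)) return(NA_real_)
  suppressWarnings(stats::wilcox.test(group_a, group_b,
                                      alternative = "two.sided")$p.value)
}

#' Bonferroni correction
#'
#' @param p_values Raw p-values.
#' @param m Number of tests (default `length(p_values)`).
#' @param alpha Family-wise level.
#' @return list(adjusted = pmin(p * m, 1), reject = p <= alpha / m).
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values), alpha = 0.05) {
  stopifnot(m >= 1)
  list(adjusted = pmin(p_values * m, 1),
       reject = !is.na(p_values) & p_values <= alpha / m)
}
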