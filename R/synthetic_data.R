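#' Behavioural generator parameters
#'
#' Parameters of the two-state (wake/sleep) renewal process used to emulate
#' DAM recordings. Run lengths are geometric (integer minutes, memoryless)
#' with phase-specific means chosen by the phase of the run's first minute.
#' Wake minutes emit Poisson beam-cross counts; sleep minutes are exactly 0.
#' In the late night a linear "sunrise anticipation" ramp multiplies the wake
#' rate, rising from 1 at `anticipation_start_zt` to `anticipation_gain` at
#' ZT24.
#'
#' Defaults approximate a healthy male fly: a few crosses per active minute,
#' moderately shorter nighttime wake runs, daytime siesta bouts of ~15 min,
#' and a 2x activity ramp over the last 3 h of the night. The nighttime wake
#' rate (3/min) keeps the probability of a silent active minute near 5%, so
#' detected zero-runs track the programmed sleep runs (a fly that is awake
#' but repeatedly missing the beam would otherwise inflate measured bout
#' durations). The nighttime sleep-bout mean is usually overridden per line
#' by the cline generator.
#'
#' @param wake_rate_day,wake_rate_night Mean crosses per active minute.
#' @param wake_bout_mean_day,wake_bout_mean_night Mean wake-run length (min).
#' @param sleep_bout_mean_day,sleep_bout_mean_night Mean sleep-run length (min).
#' @param anticipation_start_zt Ramp onset, ZT hours in [18, 24].
#' @param anticipation_gain Rate multiplier reached at ZT24.
#' @param line_sd Between-line s.d. of the log-normal multiplier applied to
#'   `sleep_bout_mean_night`.
#' @param death_prob Per-fly probability of dying mid-experiment.
#' @export
behavior_params <- function(wake_rate_day = 2.5, wake_rate_night = 3,
                            wake_bout_mean_day = 20, wake_bout_mean_night = 10,
                            sleep_bout_mean_day = 15, sleep_bout_mean_night = 30,
                            anticipation_start_zt = 21, anticipation_gain = 2,
                            line_sd = 0.15, death_prob = 0.02) {
  p <- list(wake_rate_day = wake_rate_day, wake_rate_night = wake_rate_night,
            wake_bout_mean_day = wake_bout_mean_day,
            wake_bout_mean_night = wake_bout_mean_night,
            sleep_bout_mean_day = sleep_bout_mean_day,
            sleep_bout_mean_night = sleep_bout_mean_night,
            anticipation_start_zt = anticipation_start_zt,
            anticipation_gain = anticipation_gain,
            line_sd = line_sd, death_prob = death_prob)
  if (!all(vapply(p, function(x) is.numeric(x) && is.finite(x), logical(1))))
    stop("all behaviour parameters must be finite numbers")
  stopifnot(wake_rate_day >= 0, wake_rate_night >= 0,
            wake_bout_mean_day >= 1, wake_bout_mean_night >= 1,
            sleep_bout_mean_day >= 1, sleep_bout_mean_night >= 1,
            anticipation_start_zt >= 18, anticipation_start_zt <= 24,
            anticipation_gain >= 1, line_sd >= 0,
            death_prob >= 0, death_prob <= 1)
  structure(p, class = "behavior_params")
}

# geometric run length with mean m on support {1, 2, ...}
.rgeom1 <- function(n, m) stats::rgeom(n, 1 / m) + 1L

#' Simulate one fly's beam-cross series
#'
#' Alternating wake/sleep runs starting at ZT00; each run's length is drawn
#' from the geometric distribution whose mean matches the phase (photophase /
#' scotophase) of the run's starting minute, so runs may span the phase
#' boundary. Wake-minute counts are Poisson with the minute-phase rate times
#' the anticipation ramp (scotophase only).
#'
#' @param params A [behavior_params()].
#' @param line_effect Multiplier on `sleep_bout_mean_night` (line random effect).
#' @param n_days Number of simulated days.
#' @param seed Optional integer seed (NULL uses the current RNG stream).
#' @param schedule A [light_schedule()].
#' @param fly_id,line_id,population_id,latitude Metadata for the series.
#' @param start Timestamp of the first minute (defaults to lights-on).
#' @return A [beam_series()] of `n_days * 1440` minutes starting at ZT00.
#' @export
simulate_fly_series <- function(params, line_effect = 1, n_days = 8, seed = NULL,
                                schedule = light_schedule(),
                                fly_id = "fly1", line_id = "L1",
                                population_id = "P1", latitude = NA_real_,
                                start = NULL) {
  stopifnot(inherits(params, "behavior_params"),
            is.finite(line_effect), line_effect > 0, n_days >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start))
    start <- as.POSIXct(paste("2011-09-21", schedule$lights_on), tz = "UTC")
  n <- as.integer(n_days * 1440L)

  photo_min <- schedule$photophase_hours * 60L
  zt <- (seq_len(n) - 1L) %% 1440L
  is_day <- zt < photo_min
  sbn <- params$sleep_bout_mean_night * line_effect
  if (sbn < 1) stop("effective nighttime sleep-bout mean below 1 minute")

  # draw alternating runs in batches until the series is covered
  wake_means <- c(params$wake_bout_mean_day, params$wake_bout_mean_night)
  sleep_means <- c(params$sleep_bout_mean_day, sbn)
  state <- integer(0); len <- integer(0)
  pos <- 1L
  cur <- 1L  # start awake at lights-on
  while (pos <= n) {
    batch <- 256L
    # runs drawn one at a time because the mean depends on the current phase
    for (b in seq_len(batch)) {
      ph <- if (is_day[pos]) 1L else 2L
      l <- if (cur == 1L) .rgeom1(1L, wake_means[ph]) else .rgeom1(1L, sleep_means[ph])
      state <- c(state, cur); len <- c(len, l)
      pos <- pos + l
      cur <- 3L - cur
      if (pos > n) break
    }
  }
  minute_state <- rep.int(state, len)[seq_len(n)]

  rate <- ifelse(is_day, params$wake_rate_day, params$wake_rate_night)
  ramp_start <- params$anticipation_start_zt * 60
  ramp <- rep(1, n)
  late <- !is_day & zt >= ramp_start
  ramp[late] <- 1 + (params$anticipation_gain - 1) *
    (zt[late] - ramp_start) / (1440 - ramp_start)
  counts <- integer(n)
  wake <- minute_state == 1L
  counts[wake] <- stats::rpois(sum(wake), rate[wake] * ramp[wake])

  beam_series(counts, start, schedule, fly_id, line_id, population_id, latitude)
}

#' Cline generator configuration
#'
#' Study design and programmed latitudinal cline for the nighttime
#' sleep-bout mean: `sleep_bout_mean_night = cline_intercept + cline_slope *
#' latitude`, jittered per line by a log-normal multiplier with s.d.
#' `line_sd`. The default populations and latitudes are the five American
#' collection sites (Maine to Panama City). The cline is stated on the
#' generative run-length mean; because detection truncates geometric runs at
#' 5 minutes, the *measured* mean bout duration is about the run mean + 4
#' (memorylessness), and the default slope/intercept are chosen so the
#' measured nighttime bout duration is ~50 min at 9.0°N and ~25 min at
#' 44.6°N — the two-fold equatorial/temperate contrast.
#'
#' @param populations data.frame with columns `id`, `latitude`.
#' @param cline_intercept,cline_slope Minutes, and minutes per degree N.
#' @param lines_per_pop,flies_per_line,n_days Design sizes.
#' @param seed Integer seed.
#' @export
cline_config <- function(populations = data.frame(
                           id = c("ME", "RI", "VA", "FL", "PC"),
                           latitude = c(44.62, 41.82, 37.53, 30.33, 8.97)),
                         cline_intercept = 52.29, cline_slope = -0.7013,
                         lines_per_pop = 8, flies_per_line = 16,
                         n_days = 8, seed = 1L) {
  stopifnot(nrow(populations) >= 2, all(c("id", "latitude") %in% names(populations)),
            is.numeric(cline_intercept), is.numeric(cline_slope),
            is.numeric(lines_per_pop), is.numeric(flies_per_line),
            is.numeric(n_days), is.numeric(seed) || is.integer(seed))
  pred <- cline_intercept + cline_slope * populations$latitude
  if (any(pred <= 0))
    stop("cline predicts non-positive sleep-bout mean at latitude ",
         populations$latitude[which(pred <= 0)[1]])
  structure(list(populations = populations, cline_intercept = cline_intercept,
                 cline_slope = cline_slope, lines_per_pop = as.integer(lines_per_pop),
                 flies_per_line = as.integer(flies_per_line),
                 n_days = as.integer(n_days), seed = as.integer(seed)),
            class = "cline_config")
}

#' Simulate a multi-population behavioural data set
#'
#' For each population, sets the nighttime sleep-bout mean from the linear
#' cline, draws per-line log-normal multipliers (mean 1), simulates
#' `flies_per_line` flies per line, and kills each fly mid-run with
#' probability `death_prob` (uniform death minute). Every realised parameter
#' is recorded in the truth table.
#'
#' @param config A [cline_config()].
#' @param params A [behavior_params()]; its `sleep_bout_mean_night` is
#'   overridden by the cline.
#' @return list(series = list of [beam_series()], truth = data.frame with one
#'   row per fly: ids, latitude, expected and line-level bout means, line
#'   effect, died, death_minute).
#' @export
simulate_population_set <- function(config, params = behavior_params()) {
  stopifnot(inherits(config, "cline_config"), inherits(params, "behavior_params"))
  set.seed(config$seed)
  series <- list(); truth <- list()
  for (p in seq_len(nrow(config$populations))) {
    pop <- config$populations$id[p]; lat <- config$populations$latitude[p]
    pop_mean <- config$cline_intercept + config$cline_slope * lat
    for (l in seq_len(config$lines_per_pop)) {
      line_id <- sprintf("%s_L%02d", pop, l)
      # lognormal with expectation 1 so the cline holds on average
      eff <- stats::rlnorm(1, meanlog = -params$line_sd^2 / 2, sdlog = params$line_sd)
      base <- pop_mean / params$sleep_bout_mean_night  # rescale default to cline
      for (f in seq_len(config$flies_per_line)) {
        fly_id <- sprintf("%s_F%02d", line_id, f)
        s <- simulate_fly_series(params, line_effect = base * eff,
                                 n_days = config$n_days,
                                 fly_id = fly_id, line_id = line_id,
                                 population_id = pop, latitude = lat)
        died <- stats::runif(1) < params$death_prob
        dm <- NA_integer_
        if (died) {
          dm <- sample.int(length(s$counts), 1L)
          s <- inject_dead_fly(s, dm)
        }
        series[[length(series) + 1L]] <- s
        truth[[length(truth) + 1L]] <- data.frame(
          fly_id = fly_id, line_id = line_id, population_id = pop,
          latitude = lat, expected_night_bout_mean = pop_mean,
          line_effect = eff, realized_night_bout_mean = pop_mean * eff,
          died = died, death_minute = dm, stringsAsFactors = FALSE)
      }
    }
  }
  list(series = series, truth = do.call(rbind, truth))
}

#' Zero a fly's record from its death minute onward
#'
#' Fixture for the non-informative-individual filter: a dead fly registers no
#' beam crosses.
#'
#' @param series A [beam_series()].
#' @param death_minute 1-based minute of death; beyond the series leaves it
#'   unchanged.
#' @export
inject_dead_fly <- function(series, death_minute) {
  stopifnot(death_minute >= 1)
  if (death_minute <= length(series$counts))
    series$counts[death_minute:length(series$counts)] <- 0L
  series
}

#' Genome fixture configuration
#'
#' @param n_genes Number of genes.
#' @param chrom_length Chromosome length (bp).
#' @param window_size FST window size (bp, default 1000).
#' @param outlier_fraction Fraction of windows flagged as FST outliers (0.05).
#' @param de_base_prob Per-timepoint differential-expression probability for
#'   genes outside outlier windows (length 1 or 4, timepoints ZT01/13/18/22).
#' @param de_window_enrichment Odds multiplier on DE for genes overlapping an
#'   outlier window.
#' @param direction_bias Per-timepoint probability that a DE gene is higher
#'   in population A (length 1 or 4).
#' @param fold_change_log_sd S.d. of log fold change; FC = exp(|N(0, sd)|) >= 1.
#' @param gene_length_mean Mean gene length (bp, geometric).
#' @param expressed_prob Probability a gene is expressed.
#' @param seed Integer seed.
#' @export
genome_fixture_config <- function(n_genes = 5000, chrom_length = 2e7,
                                  window_size = 1000, outlier_fraction = 0.05,
                                  de_base_prob = 0.15, de_window_enrichment = 1,
                                  direction_bias = 0.5, fold_change_log_sd = 0.7,
                                  gene_length_mean = 2000, expressed_prob = 0.9,
                                  seed = 1L) {
  stopifnot(outlier_fraction > 0, outlier_fraction < 1,
            all(de_base_prob >= 0), all(de_base_prob <= 1),
            all(direction_bias >= 0), all(direction_bias <= 1),
            expressed_prob >= 0, expressed_prob <= 1,
            de_window_enrichment > 0, chrom_length %% window_size == 0)
  structure(list(n_genes = as.integer(n_genes), chrom_length = chrom_length,
                 window_size = window_size, outlier_fraction = outlier_fraction,
                 de_base_prob = rep_len(de_base_prob, 4L),
                 de_window_enrichment = de_window_enrichment,
                 direction_bias = rep_len(direction_bias, 4L),
                 fold_change_log_sd = fold_change_log_sd,
                 gene_length_mean = gene_length_mean,
                 expressed_prob = expressed_prob, seed = as.integer(seed)),
            class = "genome_fixture_config")
}

.timepoints <- c("ZT01", "ZT13", "ZT18", "ZT22")

#' Simulate a gene table and FST window table
#'
#' Windows tile the chromosome; their mean FST values are Beta(0.8, 8) draws
#' (right-skewed, like genome-wide FST between temperate and subtropical
#' samples) and the top `outlier_fraction` are flagged. Genes are placed
#' uniformly (overlap between genes permitted) with geometric lengths; DE
#' flags per timepoint are Bernoulli with odds multiplied by
#' `de_window_enrichment` for genes overlapping a flagged window, so the
#' programmed enrichment is recoverable by the hypergeometric test.
#'
#' @param config A [genome_fixture_config()].
#' @return list(genes = data.frame(gene_id, chrom, start, end, expressed,
#'   de_ZT*, dir_ZT*, fc_ZT*), windows = data.frame(chrom, start, end,
#'   mean_fst, outlier)). Coordinates are 1-based closed intervals.
#' @export
simulate_gene_fixture <- function(config) {
  stopifnot(inherits(config, "genome_fixture_config"))
  set.seed(config$seed)
  n_win <- config$chrom_length %/% config$window_size
  windows <- data.frame(chrom = "2L",
                        start = (seq_len(n_win) - 1L) * config$window_size + 1,
                        end = seq_len(n_win) * config$window_size,
                        mean_fst = stats::rbeta(n_win, 0.8, 8))
  windows <- flag_outlier_windows(windows, config$outlier_fraction)

  ng <- config$n_genes
  if (ng * config$gene_length_mean > config$chrom_length)
    warning("expected total gene length exceeds chromosome length; genes will overlap heavily")
  len <- .rgeom1(ng, config$gene_length_mean)
  start <- floor(stats::runif(ng, 1, config$chrom_length - len + 1))
  genes <- data.frame(gene_id = sprintf("FBgn%07d", seq_len(ng)), chrom = "2L",
                      start = start, end = start + len - 1,
                      expressed = stats::runif(ng) < config$expressed_prob,
                      stringsAsFactors = FALSE)

  in_win <- genes$gene_id %in%
    overlap_genes_windows(genes, windows[windows$outlier, , drop = FALSE])
  for (i in seq_along(.timepoints)) {
    tp <- .timepoints[i]
    p0 <- config$de_base_prob[i]
    odds <- p0 / (1 - p0) * ifelse(in_win, config$de_window_enrichment, 1)
    p <- odds / (1 + odds)
    de <- genes$expressed & stats::runif(ng) < p
    dirn <- ifelse(de, ifelse(stats::runif(ng) < config$direction_bias[i],
                              "higher_in_A", "higher_in_B"), "none")
    fc <- ifelse(de, exp(abs(stats::rnorm(ng, 0, config$fold_change_log_sd))), NA_real_)
    genes[[paste0("de_", tp)]] <- de
    genes[[paste0("dir_", tp)]] <- dirn
    genes[[paste0("fc_", tp)]] <- fc
  }
  list(genes = genes, windows = windows)
}

#' Write gene and window fixtures as TSV
#'
#' @param fixture Output of [simulate_gene_fixture()].
#' @param gene_path,window_path Output paths.
#' @export
write_gene_fixture <- function(fixture, gene_path, window_path) {
  utils::write.table(fixture$genes, gene_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fixture$windows, window_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gene_path, window_path))
}
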