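# shared fixture builders and independent oracles

sched12 <- light_schedule("08:00")

# series starting exactly at lights-on
make_series <- function(counts, fly_id = "f1", line_id = "L1",
                        population_id = "P1", latitude = 40) {
  beam_series(counts, as.POSIXct("2011-09-21 08:00:00", tz = "UTC"),
              sched12, fly_id, line_id, population_id, latitude)
}

# brute-force linear-scan sleep-bout oracle, independent of rle()
brute_bouts <- function(counts, threshold = 5) {
  starts <- integer(0); durs <- integer(0)
  run <- 0L
  for (i in seq_along(counts)) {
    if (counts[i] == 0) run <- run + 1L
    else {
      if (run >= threshold) { starts <- c(starts, i - run); durs <- c(durs, run) }
      run <- 0L
    }
  }
  if (run >= threshold) {
    starts <- c(starts, length(counts) - run + 1L); durs <- c(durs, run)
  }
  data.frame(start_minute = starts, duration = durs)
}

# random DAM-like minute counts with plenty of zero runs
random_counts <- function(n = 1440, p_active = 0.4) {
  stats::rbinom(n, 1, p_active) * (stats::rpois(n, 2) + 1L)
}

# quadratic all-pairs closed-interval overlap oracle
brute_overlap <- function(genes, windows) {
  if ("outlier" %in% names(windows)) windows <- windows[windows$outlier, , drop = FALSE]
  hit <- character(0)
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(windows))) {
      if (genes$chrom[i] == windows$chrom[j] &&
          genes$start[i] <= windows$end[j] && windows$start[j] <= genes$end[i]) {
        hit <- c(hit, genes$gene_id[i]); break
      }
    }
  }
  unique(hit)
}
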