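#!/usr/bin/env Rscript

# Stage 1 — generate the behavioural data set.
#
# Simulates DAM beam-cross recordings for 5 populations (Maine 44.6°N to
# Panama City 9.0°N) x 8 isofemale lines x 16 males x 8 analysis days, with
# the programmed latitudinal cline in nighttime sleep-bout duration (about
# two-fold between 9°N and 44.6°N on the measured scale), line-level random
# effects, a pre-dawn activity ramp, and occasional deaths. Writes one DAM
# monitor file per 32 flies plus the sample sheet and truth table.

suppressPackageStartupMessages(library(sleepcline))

out_dir <- "results/simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- cline_config(seed = 20150313)
sim <- simulate_population_set(cfg)

message(sprintf("simulated %d flies (%d populations x %d lines x %d flies, %d days)",
                length(sim$series), nrow(cfg$populations), cfg$lines_per_pop,
                cfg$flies_per_line, cfg$n_days))
message(sprintf("%d flies die mid-experiment", sum(sim$truth$died)))

# pack the flies into 32-channel monitor files + a sample sheet
n_mon <- ceiling(length(sim$series) / 32)
sheet <- do.call(rbind, lapply(seq_len(n_mon), function(m) {
  idx <- ((m - 1) * 32 + 1):min(m * 32, length(sim$series))
  chunk <- sim$series[idx]
  write_dam_monitor_file(chunk, file.path(out_dir, sprintf("Monitor%02d.txt", m)))
  data.frame(monitor = sprintf("Monitor%02d", m),
             channel = seq_along(idx),
             fly_id = vapply(chunk, `[[`, character(1), "fly_id"),
             line_id = vapply(chunk, `[[`, character(1), "line_id"),
             population_id = vapply(chunk, `[[`, character(1), "population_id"),
             latitude = vapply(chunk, `[[`, numeric(1), "latitude"))
}))
write.csv(sheet, file.path(out_dir, "sample_sheet.csv"), row.names = FALSE)
write.csv(sim$truth, file.path(out_dir, "truth_table.csv"), row.names = FALSE)
message("wrote ", n_mon, " monitor files + sample sheet + truth table to ", out_dir)
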