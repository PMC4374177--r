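#!/usr/bin/env Rscript

# Stage 2 — from raw monitor files to phenotypes.
#
# Reads the DAM files written by stage 1 through the same parser a real
# experiment would use, applies the non-informative-individual filter (any
# 24 h with <= 24 beam crosses), detects sleep bouts (>= 5 min of zero
# counts), computes activity, walking speed and the sleep variables per
# phase, and aggregates fly -> line -> population.

suppressPackageStartupMessages(library(sleepcline))

in_dir <- "results/simulated"
out_dir <- "results"
stopifnot(dir.exists(in_dir))

sheet <- read.csv(file.path(in_dir, "sample_sheet.csv"))
sched <- light_schedule("08:00")
series <- unlist(lapply(unique(sheet$monitor), function(m) {
  read_dam_monitor_file(file.path(in_dir, paste0(m, ".txt")),
                        sheet, sched, monitor = m)
}), recursive = FALSE)
message("read ", length(series), " fly series")

flt <- filter_individuals(series)
message(nrow(flt$discarded), " flies discarded as non-informative; ",
        length(flt$kept), " kept")
write.csv(flt$discarded, file.path(out_dir, "discarded_flies.csv"), row.names = FALSE)

fly_df <- do.call(rbind, lapply(flt$kept, fly_phenotype))
agg <- aggregate_phenotypes(fly_df)
write_phenotype_table(fly_df, file.path(out_dir, "fly_phenotypes.csv"))
write_phenotype_table(agg$line, file.path(out_dir, "line_phenotypes.csv"))
write_phenotype_table(agg$population, file.path(out_dir, "population_phenotypes.csv"))

hourly <- hourly_population_means(flt$kept)
write.csv(hourly, file.path(out_dir, "hourly_population_means.csv"), row.names = FALSE)

night <- agg$population[agg$population$phase == "scotophase", ]
message("population mean nighttime sleep bout duration (min):")
for (i in order(-night$latitude))
  message(sprintf("  %s (%.1f N): %.1f +/- %.1f", night$population_id[i],
                  night$latitude[i], night$avg_sleep_bout_duration[i],
                  night$avg_sleep_bout_duration_sem[i]))
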