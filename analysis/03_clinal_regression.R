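#!/usr/bin/env Rscript

# Stage 3 — latitudinal cline tests.
#
# Regresses each population phenotypic mean on latitude, separately for
# photophase and scotophase, and runs the hour-by-hour scan of average sleep
# bout duration with Bonferroni correction (m = 24). The expectation under
# the programmed cline: a strong negative nighttime slope for sleep bout
# duration, nothing for daytime metrics or walking speed.

suppressPackageStartupMessages(library(sleepcline))

pop <- read.csv("results/population_phenotypes.csv")
metrics <- c("locomotor_activity", "walking_speed", "sleep_duration",
             "sleep_bout_number", "avg_sleep_bout_duration")

cline <- do.call(rbind, lapply(c("photophase", "scotophase"), function(ph) {
  d <- pop[pop$phase == ph, ]
  do.call(rbind, lapply(metrics, function(m) {
    f <- regress_on_latitude(d$latitude, d[[m]])
    data.frame(metric = m, phase = ph, slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, p_value = f$p_value, n_populations = f$n)
  }))
}))
write.csv(cline, "results/cline_regressions.csv", row.names = FALSE)

message("cline regressions (population means over latitude):")
for (i in seq_len(nrow(cline)))
  message(sprintf("  %-24s %-11s R2 = %.2f  p = %.3g", cline$metric[i],
                  cline$phase[i], cline$r_squared[i], cline$p_value[i]))

hourly <- read.csv("results/hourly_population_means.csv")
scan <- hourly_cline_scan(hourly)
write.csv(scan, "results/hourly_cline_scan.csv", row.names = FALSE)
message(sum(scan$significant_raw), " of 24 hourly regressions significant raw; ",
        sum(scan$significant_after_correction), " after Bonferroni")
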