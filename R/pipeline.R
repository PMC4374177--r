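#' Default pipeline configuration
#'
#' One list holding every tunable of the end-to-end run; the same structure
#' can be loaded from a YAML file with [load_run_config()]. Seeds make reruns
#' byte-identical.
#'
#' @param out_dir Output directory for the report tables.
#' @param seed Master seed.
#' @param n_days,lines_per_pop,flies_per_line Behavioural design sizes.
#' @param bout_threshold Sleep-bout threshold in minutes.
#' @param attribution Bout phase-boundary policy, `"split"` or `"start"`.
#' @param alpha Significance level for regressions.
#' @param outlier_fraction FST outlier fraction.
#' @param n_genes Genome fixture size.
#' @param de_window_enrichment Programmed DE enrichment odds in outlier windows.
#' @export
run_config <- function(out_dir = "results", seed = 1L, n_days = 8,
                       lines_per_pop = 8, flies_per_line = 16,
                       bout_threshold = 5, attribution = "split",
                       alpha = 0.05, outlier_fraction = 0.05,
                       n_genes = 5000, de_window_enrichment = 3) {
  list(out_dir = out_dir, seed = as.integer(seed), n_days = n_days,
       lines_per_pop = lines_per_pop, flies_per_line = flies_per_line,
       bout_threshold = bout_threshold, attribution = attribution,
       alpha = alpha, outlier_fraction = outlier_fraction,
       n_genes = n_genes, de_window_enrichment = de_window_enrichment)
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected so typos fail before any stage runs.
#'
#' @param path YAML file.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  base <- run_config()
  bad <- setdiff(names(user), names(base))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  base[names(user)] <- user
  base$seed <- as.integer(base$seed)
  base
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> exclusion filter -> sleep/activity phenotypes -> two-stage
#' aggregation -> latitude regressions and hourly scan -> ramping profiles
#' and per-bin scan -> genome fixture -> FST-window enrichment. Every stage
#' writes a CSV under `config$out_dir`, together with a provenance record
#' (config, seeds, package and R versions). Deterministic given the seed.
#'
#' @param config A [run_config()] list or path to a YAML file.
#' @return Invisible list of the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- load_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- .stage("simulate", {
    cc <- cline_config(lines_per_pop = config$lines_per_pop,
                       flies_per_line = config$flies_per_line,
                       n_days = config$n_days, seed = config$seed)
    simulate_population_set(cc)
  })

  flt <- .stage("filter", filter_individuals(sim$series))

  agg <- .stage("sleep-metrics", {
    fly_df <- do.call(rbind, lapply(flt$kept, fly_phenotype,
                                    threshold = config$bout_threshold,
                                    attribution = config$attribution))
    aggregate_phenotypes(fly_df)
  })

  cline <- .stage("cline", {
    night <- agg$population[agg$population$phase == "scotophase", ]
    fits <- lapply(.metric_cols, function(mcol) {
      f <- regress_on_latitude(night$latitude, night[[mcol]])
      data.frame(metric = mcol, phase = "scotophase", slope = f$slope,
                 intercept = f$intercept, r_squared = f$r_squared,
                 p_value = f$p_value, n_populations = f$n)
    })
    do.call(rbind, fits)
  })

  hourly <- .stage("hourly-scan", {
    hm <- hourly_population_means(flt$kept, config$bout_threshold)
    hourly_cline_scan(hm, config$alpha)
  })

  ramping <- .stage("ramping", {
    by_line <- split(flt$kept, vapply(flt$kept, `[[`, character(1), "line_id"))
    profiles <- lapply(by_line, compute_ramping_profile)
    line_pop <- vapply(by_line, function(g) g[[1]]$population_id, character(1))
    line_lat <- vapply(by_line, function(g) g[[1]]$latitude, numeric(1))
    n_bins <- length(profiles[[1]]$normalized)
    curves <- t(vapply(split(profiles, line_pop), ramping_population_curve,
                       numeric(n_bins)))
    lats <- vapply(split(line_lat, line_pop), `[`, numeric(1), 1)
    scan <- ramping_cline_scan(curves, lats[rownames(curves)],
                               bin_zt = profiles[[1]]$bin_zt)
    list(curves = curves, scan = scan)
  })

  enrich <- .stage("enrich", {
    gc <- genome_fixture_config(n_genes = config$n_genes,
                                outlier_fraction = config$outlier_fraction,
                                de_window_enrichment = config$de_window_enrichment,
                                seed = config$seed + 1L)
    fx <- simulate_gene_fixture(gc)
    ids <- overlap_genes_windows(fx$genes, fx$windows)
    list(fixture = fx, result = enrichment_report(fx$genes, ids),
         venn = timepoint_overlap_summary(fx$genes))
  })

  od <- config$out_dir
  write_phenotype_table(agg$line, file.path(od, "line_phenotypes.csv"))
  write_phenotype_table(agg$population, file.path(od, "population_phenotypes.csv"))
  utils::write.csv(flt$discarded, file.path(od, "discarded_flies.csv"), row.names = FALSE)
  utils::write.csv(cline, file.path(od, "cline_regressions.csv"), row.names = FALSE)
  utils::write.csv(hourly, file.path(od, "hourly_cline_scan.csv"), row.names = FALSE)
  utils::write.csv(ramping$scan, file.path(od, "ramping_cline_scan.csv"), row.names = FALSE)
  utils::write.csv(enrich$venn, file.path(od, "timepoint_venn.csv"), row.names = FALSE)
  er <- enrich$result
  utils::write.csv(data.frame(N = er$N, K = er$K, n = er$n, k = er$k,
                              expected = er$expected,
                              fold_enrichment = er$fold_enrichment,
                              percent_excess = er$percent_excess,
                              p_upper = er$p_upper, p_lower = er$p_lower),
                   file.path(od, "enrichment.csv"), row.names = FALSE)
  prov <- c(list(r_version = R.version.string,
                 package_version = as.character(utils::packageVersion("sleepcline")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            config)
  yaml::write_yaml(prov, file.path(od, "provenance.yaml"))

  invisible(list(simulation = sim, filtered = flt, aggregated = agg,
                 cline = cline, hourly = hourly, ramping = ramping,
                 enrichment = enrich))
}
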