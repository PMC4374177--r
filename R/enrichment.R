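#' Flag FST outlier windows
#'
#' Marks the `fraction` of windows with the highest mean FST — candidate
#' targets of spatially varying selection. Exactly `ceiling(fraction * n)`
#' windows are flagged; ties at the threshold are broken by genomic position
#' (chromosome, then start).
#'
#' @param windows data.frame with columns `chrom`, `start`, `end`, `mean_fst`.
#' @param fraction Upper-tail fraction in (0, 1), default 0.05.
#' @return `windows` with a logical `outlier` column.
#' @export
flag_outlier_windows <- function(windows, fraction = 0.05) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  stopifnot(all(c("chrom", "start", "end", "mean_fst") %in% names(windows)))
  if (any(!is.finite(windows$mean_fst))) stop("mean_fst must be finite")
  n_flag <- as.integer(ceiling(fraction * nrow(windows)))
  ord <- order(-windows$mean_fst, windows$chrom, windows$start)
  windows$outlier <- FALSE
  windows$outlier[ord[seq_len(n_flag)]] <- TRUE
  windows
}

.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

#' Genes overlapping flagged windows
#'
#' A gene counts as overlapping when its interval shares at least one base
#' pair with any flagged window; coordinates are 1-based closed intervals
#' (FlyBase/GFF style), so a gene ending at 199 does not overlap a window
#' starting at 200. Genes on chromosomes absent from the window table are
#' skipped with a warning.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param windows data.frame of windows (already subset to the flagged ones,
#'   or with an `outlier` column which is then honoured).
#' @return Character vector of unique gene ids with at least one overlap.
#' @export
overlap_genes_windows <- function(genes, windows) {
  chrom_universe <- unique(windows$chrom)
  if ("outlier" %in% names(windows)) windows <- windows[windows$outlier, , drop = FALSE]
  if (nrow(windows) == 0L) return(character(0))
  unknown <- !(genes$chrom %in% chrom_universe)
  if (any(unknown))
    warning("gene chromosome(s) absent from window table, genes skipped: ",
            paste(unique(genes$chrom[unknown]), collapse = ", "))
  g <- genes[!unknown, , drop = FALSE]
  if (nrow(g) == 0L) return(character(0))
  hits <- GenomicRanges::findOverlaps(.as_granges(g), .as_granges(windows))
  unique(g$gene_id[S4Vectors::queryHits(hits)])
}

#' Exact hypergeometric enrichment test
#'
#' Given a universe of N genes of which K carry a feature (e.g. differential
#' expression), and a sample of n genes of which k carry it, computes the
#' exact inclusive tail probabilities P(X >= k) (enrichment) and P(X <= k)
#' (depletion) of the hypergeometric distribution, plus fold enrichment
#' (k/n)/(K/N) and percent excess (fold - 1) * 100. Tails are exact down to
#' ~1e-120.
#'
#' @param N Universe size.
#' @param K Feature-positive genes in the universe.
#' @param n Sample size.
#' @param k Observed feature-positive genes in the sample.
#' @return Object of class `enrichment_result`: list(N, K, n, k, expected,
#'   fold_enrichment, percent_excess, p_upper, p_lower).
#' @export
#'
#' @examples
#' hypergeom_test(13072, 2119, 1854, 391)  # p_upper ~ 1.4e-9
hypergeom_test <- function(N, K, n, k) {
  v <- c(N = N, K = K, n = n, k = k)
  if (any(v != floor(v)) || any(v < 0)) stop("arguments must be non-negative integers")
  if (K > N || n > N) stop("K and n cannot exceed N")
  if (k < max(0, n + K - N) || k > min(n, K))
    stop(sprintf("k = %d outside support [%d, %d]", k, max(0, n + K - N), min(n, K)))
  expected <- n * K / N
  fold <- if (n == 0 || K == 0) NA_real_ else (k / n) / (K / N)
  structure(list(
    N = N, K = K, n = n, k = k, expected = expected,
    fold_enrichment = fold,
    percent_excess = (fold - 1) * 100,
    p_upper = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    p_lower = stats::phyper(k, K, N - K, n)
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment> k=%d of n=%d vs K=%d of N=%d (expected %.1f)\n  fold = %.2f (%+.1f%%), P(X>=k) = %.3g, P(X<=k) = %.3g\n",
    x$k, x$n, x$K, x$N, x$expected, x$fold_enrichment, x$percent_excess,
    x$p_upper, x$p_lower))
  invisible(x)
}

.de_cols <- function(genes) grep("^de_ZT", names(genes), value = TRUE)

.de_any <- function(genes) {
  cols <- .de_cols(genes)
  if (!length(cols)) stop("gene table has no de_ZT* columns")
  Reduce(`|`, genes[cols])
}

#' Enrichment of DE genes in a gene sample
#'
#' Builds the hypergeometric contingency from a gene table: the universe N is
#' the expressed genes, K the expressed genes differentially expressed at the
#' chosen timepoint (or any timepoint), n the expressed genes in `sample_ids`
#' and k their intersection with the DE set. Besides the excess relative to
#' the genome-wide DE proportion (`percent_excess`), the excess relative to
#' genes *outside* the sample is reported as `percent_excess_vs_outside` —
#' the two differ because the sample is part of the genome average.
#'
#' @param genes Gene table (see [simulate_gene_fixture()] / [read_gene_table()]).
#' @param sample_ids Gene ids forming the sample (e.g. from
#'   [overlap_genes_windows()] or [select_candidate_genes()]).
#' @param timepoint One of `"ZT01"`, `"ZT13"`, `"ZT18"`, `"ZT22"`, or NULL for
#'   DE at any timepoint.
#' @return An `enrichment_result` with extra field `percent_excess_vs_outside`.
#' @export
enrichment_report <- function(genes, sample_ids, timepoint = NULL) {
  expressed <- genes[genes$expressed, , drop = FALSE]
  de <- if (is.null(timepoint)) .de_any(expressed) else {
    col <- paste0("de_", timepoint)
    if (!col %in% names(expressed)) stop("no column ", col)
    expressed[[col]]
  }
  in_sample <- expressed$gene_id %in% sample_ids
  res <- hypergeom_test(nrow(expressed), sum(de), sum(in_sample),
                        sum(de & in_sample))
  n_out <- sum(!in_sample)
  prop_out <- if (n_out > 0) sum(de & !in_sample) / n_out else NA_real_
  res$percent_excess_vs_outside <-
    if (isTRUE(prop_out > 0)) ((res$k / res$n) / prop_out - 1) * 100 else NA_real_
  res
}

#' Venn partition of DE genes across timepoints
#'
#' Classifies every gene differentially expressed at one or more timepoints
#' into the non-empty subset of timepoints at which it is DE; the cells are
#' disjoint and sum to the number of DE genes.
#'
#' @param genes Gene table with `de_ZT*` columns.
#' @return data.frame: `subset` (timepoints joined by "+"), `n_timepoints`,
#'   `count`.
#' @export
timepoint_overlap_summary <- function(genes) {
  cols <- .de_cols(genes)
  tps <- sub("^de_", "", cols)
  flags <- as.matrix(genes[cols])
  de_any <- rowSums(flags) > 0
  flags <- flags[de_any, , drop = FALSE]
  key <- apply(flags, 1, function(r) paste(tps[as.logical(r)], collapse = "+"))
  tab <- table(key)
  out <- data.frame(subset = names(tab),
                    n_timepoints = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$n_timepoints, out$subset), , drop = FALSE]
}

#' Direction and magnitude of expression differences at a timepoint
#'
#' Counts DE genes higher in each population, their mean fold changes, and a
#' two-sided rank-sum comparison of the two fold-change distributions.
#'
#' @param genes Gene table with `dir_*` and `fc_*` columns.
#' @param timepoint `"ZT01"`, `"ZT13"`, `"ZT18"` or `"ZT22"`.
#' @return list(n_higher_A, n_higher_B, mean_fc_A, mean_fc_B, p_value); the
#'   p-value is NA when either side is empty.
#' @export
direction_summary <- function(genes, timepoint) {
  dcol <- paste0("dir_", timepoint); fcol <- paste0("fc_", timepoint)
  stopifnot(dcol %in% names(genes), fcol %in% names(genes))
  a <- genes[[fcol]][genes[[dcol]] == "higher_in_A"]
  b <- genes[[fcol]][genes[[dcol]] == "higher_in_B"]
  list(n_higher_A = length(a), n_higher_B = length(b),
       mean_fc_A = if (length(a)) mean(a) else NA_real_,
       mean_fc_B = if (length(b)) mean(b) else NA_real_,
       p_value = if (length(a) && length(b)) nonparametric_compare(a, b) else NA_real_)
}

#' Select candidate genes by GO keyword
#'
#' Case-insensitive substring match of keywords (e.g. "sleep", "dopamine",
#' "circadian rhythms") against GO term names; returns genes annotated to at
#' least one matching term. The mapping is a plain table — no ontology
#' traversal.
#'
#' @param go_map data.frame with columns `gene_id`, `term_name` (a `go_id`
#'   column may be present).
#' @param keywords Character vector; empty gives an empty set.
#' @return Character vector of unique gene ids.
#' @export
select_candidate_genes <- function(go_map, keywords) {
  stopifnot(all(c("gene_id", "term_name") %in% names(go_map)))
  if (!length(keywords)) return(character(0))
  tl <- tolower(go_map$term_name)
  hit <- Reduce(`|`, lapply(tolower(keywords), function(k) grepl(k, tl, fixed = TRUE)))
  unique(go_map$gene_id[hit])
}

#' Read a gene table TSV
#'
#' Expected columns: gene_id, chrom, start, end, expressed, then per-timepoint
#' de_ZT* (logical), dir_ZT*, fc_ZT*.
#' @param path TSV path.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "start", "end", "expressed")
  if (!all(req %in% names(df))) stop("need columns: ", paste(req, collapse = ", "))
  df$expressed <- as.logical(df$expressed)
  for (cl in .de_cols(df)) df[[cl]] <- as.logical(df[[cl]])
  df
}

#' Read an FST window table (BED-like TSV)
#'
#' Expected columns: chrom, start, end, mean_fst; an optional outlier column
#' is read as logical. Coordinates are 1-based closed.
#' @param path TSV path.
#' @export
read_fst_windows <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "mean_fst")
  if (!all(req %in% names(df))) stop("need columns: ", paste(req, collapse = ", "))
  if (any(df$mean_fst < 0 | df$mean_fst > 1)) stop("mean_fst must lie in [0, 1]")
  if ("outlier" %in% names(df)) df$outlier <- as.logical(df$outlier)
  df
}

#' Read a GO mapping TSV (gene_id, go_id, term_name)
#' @param path TSV path.
#' @export
read_go_mapping <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_name") %in% names(df)))
    stop("need columns gene_id, term_name")
  df
}
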