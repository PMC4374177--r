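---
title: "Methods: sleep phenotyping, cline statistics and enrichment tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep phenotyping, cline statistics and enrichment tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, definitions and numerical choices behind
`sleepcline`: what each stage computes, which conventions were adopted where
the field leaves room, and what the synthetic-data generator does and does
not emulate.

## Behavioural definitions

The raw observable is the per-minute infrared beam-cross count of one male
fly in a Drosophila Activity Monitor tube, aligned to Zeitgeber time
(ZT00 = lights-on; 12:12 LD so the photophase is ZT00–12 and the scotophase
ZT12–24). A recording "day" runs from lights-on to lights-on, and the
analysis window keeps full ZT days 5–12, dropping the acclimation period.

* **Sleep bout** — a maximal run of at least 5 consecutive minutes with zero
  beam crosses, the standard operational definition of Drosophila sleep
  (validated in the literature by arousal thresholds and
  electrophysiology). Runs touching the series boundaries count from/to the
  boundary. The threshold is a parameter (`threshold = 5`); raising it can
  only remove sleep, a monotonicity property the tests check.
* **Exclusion filter** — a fly is non-informative if *any* 24 consecutive
  hours of its record contain 24 or fewer beam crosses. All 1440-minute
  sliding windows are examined, not only ZT-aligned days: a fly that dies
  mid-day is caught a day earlier that way, and a healthy fly is never
  penalised (a fly crossing once every 55 minutes stays above the
  threshold in every window). Discarded flies are removed entirely.
* **Locomotor activity** = total phase crosses ÷ phase minutes (crosses per
  minute averaged over days). **Walking speed** = total phase crosses ÷
  minutes with at least one cross. "Inactive time" is taken as *all*
  zero-count minutes, not only minutes inside sleep bouts — the simplest
  reading; the alternative is one flag away since bouts are returned
  explicitly. Speed is undefined (NA) for a phase with no active minute and
  NAs propagate through aggregation as missing.
* **Phase-boundary bouts** — a bout that spans lights-off belongs, as a
  *bout*, to the phase of its starting minute (bout number and average bout
  duration), but its *minutes* are split between the phases for sleep
  duration (`attribution = "split"`, the default; `"start"` sends the
  minutes with the bout). The split keeps per-day sleep + wake minutes
  summing exactly to 1440, which the acceptance suite asserts.
* **Average bout duration** averages over the bouts of a phase
  (`avg_over = "bouts"`); averaging within days first is available
  (`"days"`) because the two differ when bout counts vary across days.
* **Aggregation** is strictly two-stage and unweighted: a line's value is
  the mean over its flies, a population's value the mean over its lines,
  and the s.e.m. is sd(line means)/√n_lines. With unbalanced designs this
  deliberately differs from the pooled-fly mean.

## Cline statistics

Populations — not lines or flies — are the regression units: ordinary least
squares of the population phenotypic mean on latitude, R² = 1 − SSE/SST, and
a two-sided slope t-test with n − 2 df. With five populations, residual
normality is untestable; OLS is retained with that caveat, and the
nonparametric Wilcoxon/Kruskal–Wallis tests are used for two-group
comparisons throughout because phenotype distributions are typically
non-normal. The hour-by-hour scan regresses each ZT hour's population mean
bout duration (bouts attributed to the hour of their starting minute) on
latitude and applies Bonferroni correction at m = 24.

## Sunrise anticipation and free-running rhythm

Ramping is quantified per line as the min–max-normalised late-night
activity: `(A_t − A_min)/(A_max − A_min)` over twelve 30-minute bins from
ZT18.0 to ZT23.5, where bins are averaged first across days within a fly,
then across flies within the line (the inner averaging order is fixed and
documented; it matters only with missing data). A line whose twelve bins are
flat has no defined normalisation and is excluded with a warning. Population
curves average the line curves; each bin's population means are then
regressed on latitude. Note that min–max normalisation is invariant to
rescaling, so a *linear* ramp keeps its shape whatever its gain — geographic
signal in the normalised curves comes from ramp onset timing and curve
shape, not amplitude.

Free-running period under constant darkness is estimated with a
Sokolove–Bushell chi-square periodogram: candidate periods 20–28 h in 0.1-h
steps (all integer minutes), statistic Q_P = K·Σ_h (M_h − M)²/σ² over K
complete cycles folded at P bins, compared with the χ² quantile at P − 1 df.
The significance line is Bonferroni-corrected across the 81-candidate grid
so that arrhythmic noise rarely yields a spurious period; planted periods
are recovered within one grid step, and white noise returns NA. Peak phase
folds the smoothed series (centred 60-min moving average) at the
free-running period *keeping the series start as the time origin* — the
skipped first DD day (entrainment transient, `skip_days = 1`) must not shift
the phase reference — and reports the maximum of the folded profile within
the searched half-cycle (morning: first half; evening: second half), ties
going to the earliest bin.

## Enrichment

Coordinates are 1-based closed intervals (FlyBase/GFF style) for both genes
and 1-kb F_ST windows; overlap means sharing at least one base pair, so a
gene ending at 199 does not touch a window starting at 200. "Most extreme"
F_ST is the upper tail: exactly ⌈fraction·n⌉ windows are flagged, ties at
the threshold broken by genomic position. The enrichment universe is the
*expressed* genes (matching the published ratios), tails are inclusive of
the observed count (P(X ≥ k) for enrichment, P(X ≤ k) for depletion), and
`stats::phyper` computes them exactly — stable far below 10⁻²⁵. Percent
excess is reported two ways, which genuinely differ: relative to the
genome-wide DE proportion (the convention matching the published "30% more
likely", since 21.1/16.2 ≈ 1.30) and relative to genes *outside* the
sampled windows (≈ 37% on the same counts). Per-timepoint analyses use the
all-expressed universe.

## The synthetic-data generator

The generator is a two-state renewal process in discrete minutes: wake and
sleep runs alternate, run lengths are geometric (memoryless, integer
minutes, support ≥ 1) with means chosen by the phase of the run's *starting*
minute — so runs span phase boundaries, deliberately forcing the
attribution policy to be exercised. Sleep minutes emit 0; wake minutes emit
Poisson counts at the phase rate times a linear "sunrise anticipation"
multiplier rising from 1 at `anticipation_start_zt` (default ZT21) to
`anticipation_gain` (default 2) at ZT24, scotophase only.

Parameter choices, with rationale:

* **Wake rates** (2.5/min day, 3/min night). The night rate keeps the
  probability that an awake minute registers zero crosses at ~5%. This is a
  calibration the generator's contract requires: silent wake minutes extend
  and merge detected zero-runs, and at ~20% silent minutes the measured
  bout durations no longer track the programmed sleep-run means.
  Real flies do sit still while awake; consequently real DAM data would
  need the bout threshold to absorb such minutes, a caveat for transferring
  test conclusions to real recordings.
* **The programmed cline.** The nighttime sleep-run mean is linear in
  latitude: `m(lat) = 52.29 − 0.7013·lat` minutes. Because detection
  truncates geometric runs at 5 minutes, the *measured* mean bout duration
  is approximately m + 4 (memorylessness), so these defaults put the
  measured phenotype at ≈ 50 min at 9.0°N and ≈ 25 min at 44.6°N — the
  two-fold equatorial/temperate contrast on the scale the phenotype is
  actually reported. Line effects are multiplicative log-normal
  (s.d. 0.15 on the log scale, mean 1) on the nighttime sleep mean only,
  keeping daytime clines absent, which matches the observed day/night
  decoupling. Each fly dies mid-run with probability 0.02 (uniform death
  minute), feeding the exclusion filter roughly the handful of discards per
  640 flies a real experiment shows.
* **Genome fixture.** Windows tile a 20-Mb chromosome at 1 kb; mean F_ST
  values are Beta(0.8, 8) draws (right-skewed like genome-wide F_ST between
  temperate and subtropical samples); genes are uniform with geometric
  lengths (mean 2 kb), and DE flags are Bernoulli per timepoint with odds
  multiplied by `de_window_enrichment` for genes overlapping a flagged
  window — so the programmed enrichment is exactly the quantity the
  hypergeometric machinery should recover, and multiplier 1 is an honest
  null.

What the generator does *not* emulate: temperature-dependent behaviour,
female flies, age effects, autocorrelated wake intensity, cross-timepoint
correlation of DE flags (each timepoint is drawn independently, so the
all-four-timepoints Venn cell is far smaller than in real transcriptomes),
or linkage between F_ST windows. Tests passing on this generator therefore
validate the *computational* definitions and statistics, not the biological
generality of any conclusion.

## Problem sizes and determinism

The acceptance checks use the study design (5 populations × 8 lines × 16
males × 8 days) for cline recovery over 20 seeded replicates, and
scaled-down nulls (8 lines × 2 flies × 1 day; 400-gene fixtures on a 2-Mb
chromosome) for the 500-replicate calibration runs; these sizes keep each
property estimable with tight Monte-Carlo error while the whole suite runs
in minutes. At the null-calibration sizes the slope t-test's measured size
is statistically indistinguishable from its nominal 5% — with many fewer
lines per population the skew of line effects inflates it measurably, which
is why the null design mirrors the real study's 8 lines. All simulation is
seeded; identical configurations reproduce byte-identical outputs, which
the pipeline tests assert.

## Known limitations

* The DAM reader assumes the common 42-column dialect with contiguous
  1-minute rows; column indices are configurable but sub-minute bins are
  not supported. Monitor status semantics beyond OK/not-OK are ignored;
  not-OK readings become gaps under a zero-fill-and-flag policy (default)
  or drop the whole ZT day (`"drop_day"`) — field practice varies and
  neither is asserted as canonical.
* Phase estimation reports the folded-profile maximum; multimodal profiles
  within a half-cycle resolve to the earliest maximum rather than a fitted
  component.
* The enrichment module treats the gene table's DE flags as given; calling
  differential expression from counts is out of scope, as are GO ontology
  traversal (keyword matching operates on a flat gene–term table) and
  inversion-aware null models.
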