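---
title: "Simulating signal contamination in dendro-provenancing reference chronologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating signal contamination in dendro-provenancing reference chronologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrosim)
```

## The problem

Dendro-provenancing approximates the geographic origin of timber by matching
a candidate ring-width series against a framework of regional reference
chronologies and reading the provenance off the location of the best match.
The references themselves are usually grown: a living-tree site chronology is
extended backward in time by appending the best-matching series from
historical buildings and objects. Since the true origin of historical timber
is unknown, an off-site series that happens to match well is silently
incorporated, and the reference's local growth signal is progressively
contaminated. With real data this contamination cannot even be measured.
`dendrosim` quantifies it by simulation: pseudo site signals with known
labels are generated so that every classified series can be scored against
its true origin.

## The simulation model

The model deliberately restricts itself to the year-to-year (high-frequency)
component of ring-width variability, the component that carries the
provenance signal. Each raw series is prewhitened with an autoregressive
model (`ar_residuals()`; Yule-Walker fits for orders `0..min(10·log10 n,
n-1)`, AIC selection, matching the standard prewhitening default), and the
residuals are re-centred on the raw-series mean. Per site, the residual
series are aggregated into a chronology characterised by its yearly sample
mean (`rmv`) and yearly sample SD (`rsd`, denominator `n-1`) over the common
period — the maximal consecutive year range in which *every* site has at
least 15 residual values per year (`build_param_panel()`). The common-period
length is always derived from the data, never assumed.

The `[rmv | ln(rsd)]` matrix (SDs are log-transformed because a
log-normal model fits dispersion parameters; means are left linear) is
summarised by its column means and sample covariance. New pseudo site
signals of arbitrary length are then drawn by `simulate_signal_panel()`: a
standard-normal matrix is column-centred, decorrelated exactly by an SVD
rotation, rescaled to unit SD, and pushed through the eigendecomposition
square root of the covariance. Because of the exact decorrelation step, the
*sample* covariance of the output equals the input covariance to rounding
error, not merely in expectation — the intercorrelation structure of the
site signals is bit-for-bit stable across all simulation repetitions, which
is what makes repetitions comparable. The first half of the output columns
are the yearly pseudo means (`pmv`); the second half are exponentiated into
yearly pseudo SDs (`psd`). The suite verifies `max |cor(pmv) − cor(rmv)|`
below 1e-12 over 1000 repetitions (observed: ~3e-15, i.e. rounding error).

Yearly draws are independent across years: the signals emulate AR residual
chronologies, whose innovations are serially uncorrelated by construction.
Residual autocorrelation, medium/low-frequency growth trends, missing rings
and measurement error are deliberately outside the model.

## Pseudo historical series and object chronologies

A pseudo series (`ps`) samples `Normal(pmv[t], psd[t])` over the whole
timeline (default 1000 years). It is cut into pseudo historical series
(`phs`) by drawing lengths with replacement from an empirical pool of
historical series lengths until the drawn total reaches the timeline; the
cut proceeds forward from year 1, the final piece is truncated, and a final
piece under 50 years is discarded at the analysis stage (50 years is the
minimum usable crossmatching overlap). Generation continues until every
year is covered by 30 series per site. Because every pseudo series tiles
the whole timeline (tails included), this is exactly 30 pseudo series per
site; the kept-record coverage can fall slightly below 30 in the final
decades where tails were dropped. This accounting reproduces the generated
record totals implied by the identity
`S · 30 · timeline / mean(kept length)`.

Pseudo object chronologies (`poc`) model the realistic unit of reference
construction: the mean of 6 series from one historical object. Six pseudo
series are averaged yearwise before partitioning, so an osr-1 object value
has SD `psd/√6` (verified by Monte-Carlo at 10,000 objects). The on-site
ratio (`osr`) lowers signal purity: at 0.83 one, at 0.67 two of the six
constituent series come from off-site signals. The donor of an off-site
series is drawn uniformly among the other sites, independently per series
(two off-site series may share a donor); the choice is recorded in the
dataset sidecar so sensitivity variants remain reproducible.

## The reference constructor

`make_initial_prefs()` starts one reference per site: the mean of 30 fresh
pseudo series over the most recent 150 years of the timeline, mimicking a
living-tree chronology. The placement at the timeline end is a design
choice (references are extended backward, as in practice); it is recorded
in the configuration. The initial chronology enters the reference mean
with weight 1 — one chronology, not 30 series. The alternative (counting
30) is arithmetically incompatible with sparsely replicated references
whose mean replication stays near 2 while their length exceeds the initial
window.

`run_constructor()` then iterates batch runs. Within a run, every
still-unclassified candidate is compared against the references *as of the
run's start*: Pearson correlation at the candidate's fixed calendar
position (dating is assumed correct, so there is no offset search), over
every reference overlapping it by at least 50 years, converted to
`t = r·√(n−2)/√(1−r²)`. The candidate is assigned to the reference with
the highest t among those reaching the threshold (grid: 5, 10, 15, 20).
All accepted candidates are added simultaneously at the run's end, and
runs repeat until none is accepted or no candidates remain. A
classification is final; members are never re-scored against the updated
references. Numerical conventions: `t` at `|r| = 1` is capped at 1e6
(preserves ordering, avoids infinities); exact t ties break to the lowest
reference index (probability ~0 with continuous data, but makes the trace
deterministic); a reference value exists for any year with at least one
contributor; zero-variance overlaps are skipped. Termination is
guaranteed — every continuing run removes at least one candidate from a
finite pool — and the suite checks the run-1 assignments against an
independent brute-force scorer.

## Evaluation

Per repetition: the percentage of generated series classified, the
percentage of classified series classified correctly (denominators:
classified/generated and correct/classified; a repetition with zero
classifications reports 0% correct with a flag rather than 0/0), runs
executed, and per-reference length (count of covered years), mean
replication, and contamination. Contamination is the percentage of a
reference's members originating from a contrast group other than the
group of its initializing signal, under four groupings: site, elevation
band (low/medium/high), coarse elevation (high vs the rest) and watershed.
Coarsening can only merge groups, so site-level contamination bounds every
other contrast from above; contamination of an empty reference is reported
as 0 with an `empty` flag so tables stay rectangular. It is cumulative
over all members classified so far, consistent with monotone per-run
trajectories.

Across repetitions, `summarize_repetitions()` reports min/median/max of
the headline statistics, per-run 95th-percentile contamination and median
length/replication restricted to *fully replicated* runs (runs executed in
every repetition — later runs exist only in some repetitions and would
bias per-run statistics), and mean counts of references per length
category (thirds of the timeline, full length, and `0` meaning "attracted
no series": initial references are 150 years long, so a length category of
0 can only mean zero members) and per attractor category (0–100, 101–500,
501–1000, >1000 series). The 95th percentile uses linear interpolation
between order statistics (R quantile type 7); the convention is recorded
here because percentile rules differ between software.

Signal stability is tracked by two ranges: the pmv-vs-rmv correlation
difference (machine precision by construction, see above) and the
spmv-vs-rmv difference, where `spmv` are the mean chronologies under a
*perfect* classification — the irreducible sampling variability of 30-fold
replicated chronologies, against which constructor-induced contamination
must be judged.

## The synthetic fixture

The package tests and the acceptance script run on a synthetic stand-in
for a real network (`fixture_spec()`), since the deposited spruce dataset
cannot be redistributed. Its defaults are the study conditions: 15 sites
with 15–32 series each, all ending in 2014 with lengths 70–110 years so
that a ~60–70-year common period at 15-fold replication emerges from the
data; site signals correlated in elevation blocks (7 low, 5 medium, 3
high; within-block r = 0.75, low–medium r = 0.5, high-vs-rest r = 0.3 —
a distinct high-elevation cluster over a broadly intercorrelated lowland
group, the qualitative structure that drives elevation-specific results);
within-site between-tree correlation rbar = 0.3, the conventional value
for conifer networks, giving tree noise ≈ 1.53× signal SD; AR(1)
persistence 0.5 in the raw widths so prewhitening has real work to do;
log-normal widths `1.5·exp(0.3·x)` mm, which guarantees positivity and is
a standard distributional assumption for ring widths; and a truncated
log-normal length pool (median ~70, minimum 50, maximum 1000 years)
emulating a laboratory collection of historical series.

What the fixture does *not* emulate: real spatial correlation decay,
climate forcing, age trends, missing rings, or the heavy upper tail of
real historical series lengths. Passing tests therefore demonstrate the
correctness and internal consistency of the machinery and the qualitative
behaviour of the constructor (separability, degradation, contamination
dynamics), not quantitative contamination rates for any real region —
those require the real network's parameter panel.

Two analytic toys are used where exact control matters:
`toy_param_panel()` builds a panel directly from a prescribed between-site
correlation and constant SD. Separability uses 15 orthogonal signals with
near-zero noise (all classifications must be correct and uncontaminated);
degradation raises the between-signal correlation to 0.95 under the
rbar-0.3 noise level, which drives median correctness far below 50% — with
near-zero noise every candidate would still correlate ~1 with its own
signal and ~0.95 with the others and classification would stay perfect,
so realistic noise is what makes near-collinear signals confusable. The
15-signal configuration matches the study design; a 3-signal toy would put
chance-level correctness at 33% and mask the degradation.

## Problem sizes

The suite and the acceptance script choose sizes that keep a full run on
one CPU in minutes while leaving every mechanism exercised at the design
scale where it matters: covariance fidelity at the full 15-site panel and
1000-year timeline over 1000 repetitions; partition accounting over
10,000 random pools; the variance law over 10,000 objects; constructor
experiments at the full 15-site/1000-year/30-replication scale with 3
repetitions in the acceptance script and reduced (200-year, 5-replication)
scales in the property tests; `run_experiment()` exposes the full
1000-repetition design as configuration for users with the compute budget.

## Known limitations

* The t-value uses the plain Pearson correlation of the provided values;
  no Baillie–Pilcher-style renormalisation is applied, since the pseudo
  series already emulate prewhitened residuals.
* No offset search: candidates are assumed correctly dated.
* One intercorrelation structure is assumed for the whole timeline;
  temporal variability of between-site similarity is not modelled.
* Repetitions are embarrassingly parallel but executed sequentially;
  per-repetition seeds are derived from the root seed, so any execution
  order (or future parallel backend) yields identical results.
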