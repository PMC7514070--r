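# dendrosim

Simulation of signal contamination in dendro-provenancing reference
chronologies.

## The problem

Dendro-provenancing approximates where a piece of timber grew by matching
its ring-width series against regional reference chronologies. References
are usually grown from living-tree site chronologies by repeatedly
appending the best-matching series from historical buildings and objects —
series whose true origin is unknown. Every off-site series that slips in
dilutes the reference's local growth signal, and with real data this
contamination cannot even be measured, because there is no ground truth for
historical timber. `dendrosim` measures it by simulation: pseudo site
signals with known labels are generated from the statistical properties of
a real site-chronology network, pseudo "historical" series are sampled from
them, references are grown algorithmically, and every classification is
scored against its true origin.

The package is aimed at dendrochronologists and archaeometrists who want to
assess, *before* field work and provenancing, whether their network of site
chronologies supports uncontaminated references — and at which similarity
thresholds.

## The model in brief

* **Parameter panel.** Each raw series is AR-prewhitened (AIC-selected
  Yule-Walker order); per site and year, the residuals across trees give a
  sample mean *rmv* and SD *rsd* over the common period (every site ≥ 15
  trees per year).
* **Pseudo site signals.** The column covariance Σ of `[rmv | ln(rsd)]` is
  eigendecomposed, Σ = EΛEᵀ, and an exactly decorrelated standard-normal
  matrix is mapped through μ + Z(EΛ^1/2)ᵀ. The *sample* covariance of the
  result equals Σ to rounding error, so the between-site correlation
  structure is identical in every repetition (observed deviation ~10⁻¹⁵).
  Columns 1..S are yearly pseudo means *pmv*; columns S+1..2S exponentiate
  into yearly pseudo SDs *psd*.
* **Candidates.** A pseudo series draws Normal(pmv[t], psd[t]) over a
  1000-year timeline and is cut into pseudo historical series (*phs*,
  ≥ 50 years) using an empirical pool of series lengths; pseudo object
  chronologies (*poc*) average 6 pseudo series first, with an on-site
  ratio (1, 0.83, 0.67) controlling how many of the six are off-site.
* **Constructor.** One initial reference per site (mean of 30 fresh pseudo
  series over the most recent 150 years). In batch runs, every unclassified
  candidate is correlated with every reference overlapping it by ≥ 50 years
  at its fixed calendar position, scored by `t = r·√(n−2)/√(1−r²)`, and
  assigned to the highest-t reference above the threshold (grid: 5, 10,
  15, 20). Accepted candidates extend the references; runs repeat to a
  fixpoint.
* **Evaluation.** Percent classified, percent of classified correct, and
  per-reference contamination — the share of members from another site,
  elevation band, or watershed than the initializing signal — tracked per
  run and aggregated over many repetitions (95th percentiles over fully
  replicated runs, length/attractor categories).

Everything runs on a built-in synthetic fixture (15 correlated sites,
15–32 trees each), so no external data are needed.

## Worked example

```r
library(dendrosim)

spec  <- fixture_spec(n_sites = 6, block_sizes = c(low = 3, medium = 2, high = 1))
raw   <- make_raw_dataset(spec, seed = 7)      # synthetic multi-site RWL data
panel <- build_param_panel(raw)                # AR residuals -> rmv/rsd panel
panel
#> <param_panel> 6 sites x 73 years (1942-2014)

pool <- make_length_pool(spec, n = 500, seed = 8)
sig  <- simulate_signal_panel(panel, n_years = 1000, seed = 9)
round(delta_corr(sig$pmv, panel$rmv), 17)      # covariance preservation
#>       min       max
#> -1.44e-15  4.40e-16

phs <- build_phs_dataset(sig, pool, target_replication = 30, seed = 10)
phs
#> <pseudo_dataset> 2230 phs records, 6 sites, 1000 pseudo years (target repl. 30)

cc    <- constructor_config(t_threshold = 5)
prefs <- make_initial_prefs(sig, cc, seed = 11)
res   <- run_constructor(phs, prefs, cc)
summ  <- repetition_summary(res, phs, contrast_map(fixture_site_meta(spec)))
summ
#> <repetition_summary> 2230 generated, 8.21% classified, 96.72% of those correct, 6 runs

summ$per_pref[, c("init_site", "n_members", "length", "mean_replication",
                  "contamination_site", "contamination_elevation")]
#>   init_site n_members length mean_replication contamination_site contamination_elevation
#> 1    site01        41    257        14.618677           2.439024                       0
#> 2    site02        22    232         8.103448           4.545455                       0
#> 3    site03        25    212        11.141509          12.000000                       0
#> 4    site04        19    184         9.592391           0.000000                       0
#> 5    site05        46    240        16.229167           2.173913                       0
#> 6    site06        30    204        13.539216           0.000000                       0
```

Reading the output: of 2230 generated pseudo historical series, 8.2%
cleared the `t ≥ 5` threshold over a ≥ 50-year overlap and were classified;
96.7% of those went to the reference initialized with their true source
signal. Each reference grew from its initial 150 years to ~180–260 years;
site-level contamination stayed below 12%, and under the elevation
contrast the references are clean — off-site members came from the same
elevation band, the typical pattern when within-band signal correlation is
high. `run_experiment()` repeats such a pipeline over many repetitions
with derived seeds and aggregates the tables; `compare_settings()` lines
up approaches (phs/poc, thresholds, on-site ratios) side by side.

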