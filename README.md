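# wolfmon

Analytics for documenting the recolonization of a large carnivore — the
grey wolf is the motivating case — from the three data streams a
monitoring programme typically has: verified opportunistic occurrence
records, camera-trap detection logs, and scats collected along transects.
The package is aimed at wildlife ecologists who need the full chain from
raw records to publishable summaries to be explicit, deterministic and
testable.

## What it computes

**Filtering.** Occurrence records carry SCALP reliability codes (C1 hard
evidence, C2 expert-confirmed, C3 unconfirmed); C3 records are dropped.
Pseudo-replication is removed by keeping one record per locality and day,
and by thinning camera detections with a rolling 30-minute independence
window per site and species. Pup records are clustered into unique
reproduction events by single linkage with a strict 20-km threshold
within each calendar year.

**Grid occupancy.** A 10 × 10 km half-open grid is classified per
multi-year period. A year *qualifies* with ≥1 C1 or ≥2 C2 records in a
cell; a cell is *Permanent* when qualifying years reach
`ceiling(length/2)` (3 of 5) or a reproduction event occurred in the last
three years of the period, *Sporadic* with any lesser presence, *Absent*
with none. Between-period change is reported as `100 (n₂ − n₁)/n₁`.

**Diel activity and overlap.** Detection times are mapped to the circle
and smoothed with von Mises kernels whose concentration follows Taylor's
plug-in rule κ\* = [3n κ̂² I₂(2κ̂) / (4√π I₀(κ̂)²)]^(2/5). Temporal overlap
between species pairs is the coefficient of overlapping
Δ = ∫ min{f₁, f₂}, estimated by the large-sample density-ratio estimator
Δ̂₄ and checked against direct numerical integration (Δ̂₁); coefficients
classify as low (< 0.50), moderate (0.50–0.75) or high (> 0.75). The
relative abundance index is RAI = 100 × detections / trap-nights.

**Diet.** Frequency of occurrence of food items and of the five fixed
categories (livestock, wild prey, pet, fruit, other) is the percentage of
scats containing the unit, with percentile bootstrap confidence intervals
(B = 1000). The Brillouin index HB = (ln N! − Σ ln nᵢ!)/N accumulated
over randomized scat orderings gives the minimum sample size: the
smallest k whose averaged incremental change stays below 1%.

**Model selection.** Permanent vs Sporadic status is modelled by binomial
logistic regression over all subsets of the covariates that survive a
|r| > 0.7 collinearity screen. Models are ranked by
AICc = −2 log L + 2k + 2k(k+1)/(n−k−1); Akaike weights
ωᵢ = exp(−Δᵢ/2)/Σ exp(−Δⱼ/2) are normalized over all candidates, and
competitors (Δ < 2) are model-averaged (full averaging by default).

**Synthetic data.** `simulate_inputs()` generates all inputs from one
master seed — covariates in realistic ranges, occupancy linked to them
through a logistic model with a rising year trend (a recolonization
front), von Mises mixture activity times, multinomial scat contents — so
the whole pipeline runs and is testable without any field data.

## Worked example

```r
library(wolfmon)

sim <- simulate_inputs(sim_config(seed = 42))

# filter, classify, summarize occupancy
occ   <- daily_independence(filter_scalp(sim$occurrences))
repro <- cluster_reproductions(occ)
ps    <- list(period("2015-2019", 2015, 2019),
              period("2020-2024", 2020, 2024))
st    <- classify_grid(sim$grid, occ, ps, repro)
summarize_occupancy(st)
#> Grid occupancy by period:
#>     period n_permanent n_sporadic n_occupied
#>  2015-2019          11         21         32
#>  2020-2024          29         13         42
#> Net change 2015-2019 -> 2020-2024:  Permanent +163.6%,  Sporadic -38.1%,  Occupied +31.2%
```

The simulated population spreads: occupied cells rise from 32 to 42 and
Permanent cells from 11 to 29 between the two five-year periods, the
signature of an establishing population (sporadic cells convert to
permanent ones).

```r
det  <- camera_independence(sim$detections)
wolf <- detection_series("wolf", "all",
                         time_to_angle(det$timestamp[det$species == "wolf"]))
fox  <- detection_series("red_fox", "all",
                         time_to_angle(det$timestamp[det$species == "red_fox"]))
delta4(wolf, fox)
#> Temporal overlap wolf vs red_fox (n = 466, 491):
#>   Dhat4 = 0.909 (high); reference integral Dhat1 = 0.908
```

Both simulated species are nocturnal, so their activity curves overlap
almost completely; the density-ratio estimate and the numerical integral
agree to three decimals.

```r
bootstrap_fo_ci(sim$scats, B = 1000, seed = 1)
#>        unit  n        fo    ci_low  ci_high
#> 1 livestock 28 37.333333 25.333333 48.00000
#> 2 wild prey 45 60.000000 48.000000 70.66667
#> 3       pet 32 42.666667 32.000000 54.66667
#> 4     fruit 11 14.666667  6.666667 22.66667
#> 5     other  4  5.333333  1.333333 10.66667

min_sample_size(sim$scats, orderings = 100, seed = 2)
#> Brillouin accumulation over 75 scats (100 orderings):
#>   minimum sample size: 26 (change < 1% thereafter)
```

Livestock occurs in 28 of 75 simulated scats (FO 37.3%, 95% CI
25.3–48.0); about 26 scats would have sufficed for a stable diversity
estimate under these conditions.

`run_pipeline(pipeline_config(seed = 1))` chains every stage and writes
CSV/GeoJSON/JSON outputs stamped with a config hash.

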