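# spinedyn

Quantification toolkit for neuronal imaging studies of dendritic spines and
RNA-granule transport. Studies in this area report a recurring set of
derived numbers — spine-class densities, five-way granule motion fractions,
longitudinal formation/elimination rates, puncta distribution profiles,
behavioral indices, LTP magnitudes — each defined by simple rules applied
to manually measured tables. `spinedyn` implements those rules as tested,
reusable functions, together with seeded synthetic-data generators that
carry ground-truth labels so every stage can be validated by parameter
recovery without any external data.

## What it computes

**Spine morphometry.** A protrusion with length *L*, head width *H*, neck
width *N* (μm) is classified from its ratios: mushroom (H/N ≥ 1.5),
filopodium (H/N < 1.2 and L/N > 3), stubby (H/N ≤ 1 and L/N ≤ 1), thin
(1 ≤ H/N < 1.5 and 1.5 ≤ L/N ≤ 3); anything outside all four regions is
explicitly `unclassified`. Densities are count / dendrite length × 10 μm,
averaged per neuron.

**Granule motion.** A kymograph trace (time, position polyline) is reduced
to net displacement ND (endpoint difference, signed away from the soma) and
lateral maximal displacement LMD (position range). |ND| ≥ 2 μm is
unidirectional (anterograde if ND > 0, retrograde if ND < 0); otherwise
LMD < 1 μm is stationary, 1 ≤ LMD < 2 μm oscillatory, LMD ≥ 2 μm
bidirectional. Motility metrics: travel distance Σ|Δx|, maximal velocity
max|Δx/Δt|, maximal run length (largest displacement at constant velocity).

**Spine turnover.** Protrusions at imaging days 0/2/7 are filtered
(length > shaft diameter / 3), split into spines vs filopodia, matched
across days by greedy nearest-neighbor on arc position, and summarized as
formation/elimination percentages (first-view denominator), turnover,
survival of newly formed spines, and re-formation of eliminated spines in
close proximity.

**Puncta distributions.** mRNA puncta positions are binned at 5 μm from the
cell body, normalized to the first bin, and averaged bin-wise across
dendrites (mean ± SEM), plus linear densities.

**Study scores.** Discrimination index, sociability/social-memory
preference index, marble burying score, LTP magnitude (% change over the
50–60 min post-induction window) and paired-pulse ratios.

## Worked example

```r
library(spinedyn)
library(dplyr)

sim <- sim_longitudinal_spines(seed = 2)   # 200 spines, 3 imaging days
summarize_turnover(sim$observations) |>
  select(window, n_first, formation_pct, elimination_pct,
         turnover_pct, survival_pct, reformation_pct)
#>      window n_first formation_pct elimination_pct turnover_pct survival_pct reformation_pct
#> 1 day0-day2     200      6.500000            11.5    18.000000          100              NA
#> 2 day2-day7     190      3.157895             0.0     3.157895           NA        83.33333
```

Day 0 starts with 200 spines; 23 are eliminated and 13 formed by day 2
(11.5% and 6.5% of the first view), giving an 18% turnover for the window.
All 13 newly formed spines are still present at day 7 (100% survival), and
5 of the 6 spines formed in the second window (83.3%) appear within 2 μm of
a position where a spine was eliminated in the first window — the
re-formation readout. Those counts equal the generator's event ledger
(`sim$events`) exactly.

Classifying simulated granule traces:

```r
traj <- sim_trajectories(n_per_class = 4, seed = 2)
classify_traces(traj$traces)
#> # A tibble: 20 × 10
#>   dendrite_id granule_id n_points duration_s    nd_um lmd_um travel_um ...
#> 1 sim         g0001           100         99 -0.0827   0.223      4.71
#> 2 sim         g0002           100         99  0.00187  0.210      5.47
#> ...
```

with a `motion_class` column holding the five-way label; accuracy against
the generator's ground truth is 100% at the default noise level.

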