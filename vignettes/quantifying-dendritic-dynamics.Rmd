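---
title: "Quantifying dendritic spine morphology, granule transport and spine turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dendritic spine morphology, granule transport and spine turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedyn)
library(dplyr)
```

`spinedyn` packages the downstream quantification used in studies of
dendritic mRNA transport and synaptic plasticity: given manual measurements
(spine geometries, kymograph polylines, longitudinal protrusion maps, puncta
positions, behavioral durations, fEPSP sweeps), it computes the classifier
labels and summary rates those studies report. Image segmentation, tracing
and event detection stay upstream; this package starts where the tables
begin. Every stage has a seeded generator producing inputs with known ground
truth, so the whole pipeline is testable by parameter recovery without any
external data.

## Spine morphometry

A protrusion measured as length $L$, head width $H$ and neck width $N$ (all
in μm) is classified by its ratios $H/N$ and $L/N$:

* **mushroom**: $H/N \ge 1.5$
* **filopodium**: $H/N < 1.2$ and $L/N > 3$
* **stubby**: $H/N \le 1$ and $L/N \le 1$
* **thin**: $1 \le H/N < 1.5$ and $1.5 \le L/N \le 3$

The four regions are mutually exclusive except on their shared boundaries,
but they do not tile ratio space. Two design choices follow. First, the
rules are evaluated in a fixed order (mushroom, filopodium, stubby, thin) so
behavior exactly on a boundary is deterministic; placing filopodium second
keeps the $H/N \in [1, 1.2), L/N > 3$ corner from being absorbed by a
sloppily widened thin rule. Second, ratio combinations outside all four
regions (e.g. $H/N = 1.3$, $L/N = 4$) get an explicit `unclassified` label:
they are excluded from per-class densities but still counted in totals,
never silently dropped. Comparisons are implemented exactly as printed
($\ge$, $\le$, strict $<$, $>$) in double precision with no epsilon
adjustment, which is what makes boundary sweeps reproducible.

Densities are `count / dendrite_length × scale` with a default reporting
scale of 10 μm; per-μm values are just `scale = 1`. Dendrites are flagged
eligible when longer than 50 μm, and neuron-level summaries average
dendrite densities because the experimental unit is the neuron.

## Granule motion from kymograph traces

A trace is an ordered (time, position) polyline, position in μm along the
dendrite with positive pointing away from the soma (recordings with the
soma on the right are flipped at ingest; pixel coordinates are converted
using the recording's pixel size). Two displacement statistics decide the
class: net displacement **ND** (last minus first position, signed) and
lateral maximal displacement **LMD** (range of positions). Traces with
$|ND| \ge 2$ μm are unidirectional — anterograde when $ND > 0$, retrograde
when $ND < 0$; the magnitude reading is forced by the fact that retrograde
traces have negative ND yet are defined inside the unidirectional branch.
Everything else is stationary (LMD < 1 μm), oscillatory (1 ≤ LMD < 2 μm) or
bidirectional (LMD ≥ 2 μm).

Motility metrics: *travel distance* is the spatial path length
$\sum |\Delta x|$. The alternative reading — Euclidean length in the
kymograph plane — would mix μm and seconds, so the spatial reading is
adopted (and flagged here as a choice). *Maximal velocity* is the largest
absolute per-segment slope $|\Delta x / \Delta t|$. *Maximal run length* is
the largest position change over a maximal block of consecutive segments
moving in one direction at constant velocity. Manual polyline traces are
already piecewise-constant in velocity, so "constant" is implemented as an
absolute tolerance (default 0.02 μm/s against the block's first segment,
sign constancy required, pauses terminate runs); the tolerance only merges
near-identical segments and is configurable because no published value
exists. These definitions imply, for every trace,
$|ND| \le LMD \le$ travel distance, run length $\le$ travel distance, and
max velocity $\ge$ mean speed — enforced as property tests.

Traces shorter than the full 100 s recording are analyzed over their own
duration, since manual traces need not span every frame.

## Longitudinal spine turnover

Protrusions observed on imaging days 0/2/7 are first filtered (length
strictly greater than one third of the shaft diameter), then split into
spines and filopodia (head/neck < 1.2 and length/neck > 3; the
"twice the average spine length" criterion is optional and off by default
because it is stated as a tendency). Filopodia are tallied separately and
excluded from turnover counts.

The published analysis matches spines across days by eye from 3-D stacks;
any algorithmic matching is therefore this package's convention. We use
greedy nearest-neighbor matching on arc position: all cross-day pairs
within the match radius (default 0.5 μm) are sorted by distance and
accepted one-to-one. This is deterministic, order-independent, symmetric up
to transposition, and exact whenever inter-spine spacing is large relative
to the radius. Formation and elimination percentages divide the formed and
eliminated counts by the first-view spine count; total turnover defaults to
their sum, with the pooled alternative `(formed + eliminated) / (2 × N)`
selectable since no formula is printed for it. Zero first-view spines yield
flagged `NA` rates, never a silent zero. Survival of newly formed spines is
the percentage still matched at the third day. Re-formation counts
window-2 formed spines within a proximity (default 2.0 μm — on the order of
inter-spine spacing; unquantified in the literature, so configurable and
echoed into run metadata) of a window-1 eliminated position, expressed
relative to the window-2 formed count by default.

## Dendritic puncta distributions

Puncta positions (μm from the cell body along the straightened dendrite)
are binned at 5 μm in half-open bins $[iw, (i+1)w)$ with the last bin
closed at the dendrite tip, so each punctum lands in exactly one bin and
totals are conserved. Profiles are normalized to the first bin; a dendrite
whose first bin is empty has no defined normalization and is flagged and
excluded from the group mean rather than dividing by zero (the edge-bin
convention and the empty-first-bin rule are unstated upstream and fixed
here). Group profiles are bin-wise means ± SEM of per-dendrite normalized
counts, matching figure-style presentation; linear density is
`count / length × scale`.

## Behavioral and electrophysiological scores

* Discrimination index: novel / (novel + familiar) interaction time.
* Sociability and social-memory indices share one core,
  $(A - B)/(A + B)$. The printed formula has a dangling division — read
  literally it would subtract a dimensionless ratio from a time — so the
  normalized-contrast parse is used; it is bounded in $[-1, 1]$ and
  antisymmetric.
* Marble burying: per-marble scores 4/3/2/1/0 summed over the cage
  (20 marbles standard, configurable).
* LTP magnitude: percent change of mean fEPSP amplitude in the 50–60 min
  post-induction window relative to the 30 min baseline mean. Baseline uses
  $[-30, 0)$ so the induction time point itself is excluded.
* Paired-pulse ratio: mean of per-sweep amp2/amp1 ratios within each
  inter-stimulus interval (mean-of-ratios, matching the "average ratio"
  convention).

## Synthetic data: what it emulates, and what it does not

Generators are pure functions of their seed (RNG state is scoped with
`withr::with_seed`, no hidden globals). Their defaults are the study
conditions the tests run under:

* **Trajectories** (`sim_trajectories()`): 100 frames at 1 frame/s.
  Stationary granules are Gaussian jitter (SD 0.05 μm — sub-pixel, well
  inside the 1 μm band). Oscillatory traces are reflected random walks in a
  1.5 μm band (a sinusoid mode exists but the walk is the default, so the
  classifier is not handed an artificially clean frequency signature);
  bidirectional traces are ±0.08 μm/s sign-switching walks (switch
  probability 0.1/frame); anterograde/retrograde traces are 0.08 μm/s runs
  with 0.2/frame pause probability. Noiseless paths are resampled until
  they sit well inside their class bands (oscillatory range in [1.2, 1.7]
  μm, bidirectional range ≥ 2.3 μm with |ND| ≤ 1.4, directed |ND| ≥ 2.5),
  so ground-truth labels never depend on the realized measurement noise;
  jitter is added afterwards.
* **Spine populations** (`sim_spine_population()`): ratio boxes strictly
  interior to each class region, so label recovery is exactly 100% and any
  disagreement is an implementation defect, not sampling noise.
* **Longitudinal maps** (`sim_longitudinal_spines()`): 200 day-0 spines on
  a 5 μm grid (spacing ≫ the 0.5 μm match radius), elimination probability
  0.10, formation 0.05 per window, re-formation fraction 0.5. Re-formed
  spines are placed 0.2–1.5 μm from a distinct eliminated ancestor
  (inside the 2 μm proximity); other formations at gap midpoints, 2.5 μm
  from every original position (outside it). Observed positions carry
  0.05 μm remeasurement noise. An event ledger records every elimination,
  formation and re-formation with ancestor links.
* **Puncta** (`sim_puncta()`): Poisson counts placed uniformly or with
  exponential distance decay via the truncated inverse CDF.

What passing recovery tests show is that the pipeline's estimators are
consistent for data that match their assumptions: well-separated spines,
unambiguous traces, noise well inside the decision bands. Real data violate
these in ways the generators deliberately do not model — crowded spines
closer than the match radius, traces near class boundaries, uneven
kymograph intensity, out-of-focus structures — so recovery on synthetic
data validates the arithmetic and the conventions, not performance on
difficult images. Group effect sizes between genotypes are likewise not
emulated; generators target the assumed statistical structure, not the
biology.

## Problem sizes and numerical conventions

The test suite runs the classifier-vs-oracle comparison on 10^4 random
traces and a dense ratio grid, and turnover recovery on 20 seeds × 200
spines — sizes at which binomial 95% confidence intervals are a few
percentage points wide, chosen so the whole suite completes in seconds.
Boundary sweeps round their grids to 10 decimals before classification so
that accumulated floating-point error (e.g. `1.5 + 15 * 0.1` exceeding 3 by
4e-16) cannot move a grid point across a printed cutoff. Degenerate inputs
are flagged, not coerced: empty measurement lists give zero counts, empty
first bins and zero first-view counts give `NA` with a warning, and
malformed traces (under two points, non-increasing time) are errors.

## A full run

```{r example}
sim <- sim_longitudinal_spines(seed = 2)
summarize_turnover(sim$observations) |>
  select(window, n_first, formation_pct, elimination_pct,
         turnover_pct, reformation_pct)
sim$truth[c("n_eliminated_w1", "n_formed_w1", "n_formed_w2", "n_reformed_w2")]
```

The pipeline's counts reproduce the generator's event ledger exactly;
across seeds the estimated rates recover the generating probabilities
within binomial sampling error, which is the strongest statement the study
design supports.

## Known limitations

* Matching, proximity and the turnover formula are conventions (the
  upstream procedure is manual); results should always be reported with the
  run metadata that records them.
* Greedy matching is not globally optimal; for spacing comparable to the
  match radius a Hungarian assignment could differ. At realistic spine
  spacing the two coincide.
* The run-length tolerance is not identifiable from published material;
  sensitivity to it should be checked when comparing across datasets.
* Only descriptive summaries are produced; between-group inference is out
  of scope.
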