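---
title: "Modelling continental human dispersal and correcting sparse date records"
author: "paleospread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling continental human dispersal and correcting sparse date records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleospread)
```

`paleospread` couples a forward stochastic model of human colonisation of a
palaeo-continent with an inverse estimator that converts sparse, biased
archaeological dates into a first-arrival surface the model can be ranked
against. This vignette explains the model, its assumptions, the tunable
parameters, the numerical choices, and what the synthetic-data experiments
do and do not demonstrate.

## 1. The cellular automaton

The landscape is a 0.5° × 0.5° lattice (86 rows × 87 columns by default,
rows indexed north to south; one cell is 3080.25 km², nominally
0.5 × 111.12 = 55.56 km wide). Time advances in human generations of
27.9 yr. The environment is supplied as 1000-year slices — land mask from an
elevation field against a sea-level series (plus a separately tracked lake
basin that can flood into a movement barrier), and net primary production
(NPP, kg C m⁻² yr⁻¹) — and interpolated linearly between slices at each
generation's age; the land mask uses the nearest slice.

**Growth.** Each cell follows a Ricker update
`N' = N exp(r_m (1 − N/K))`, stochastically rounded (floor plus a Bernoulli
draw on the fraction) so people stay countable without biasing the
expectation. The maximum growth rate defaults to `r_m = 0.205`, the midpoint
of the plausible 0.10–0.31 per-generation range; it is a free parameter of
the sensitivity analysis, not a fitted quantity.

**Carrying capacity.** NPP is translated into people per cell through one of
three relationships, all anchored to the ethnographic density bounds
0.018–1.152 people km⁻²:

* *linear* — global min–max rescale of NPP onto the density bounds times
  cell area. "Global" means over all land cells of **all** slices, so a
  cell's K is comparable through time;
* *rotated parabolic* — on normalized NPP `p ∈ [0, 1]`,
  `K ∝ a (p − h)² + ½` with `a = −3` and `h` the median of `p`, clamped at
  zero, peaking at half the linear maximum: mid-productivity ecotones carry
  the highest densities;
* *reciprocal quadratic yield density* — `K ∝ P/(a + bP + cP²)`
  (`a = 200, b = 0.6, c = 0.2`), with normalized NPP mapped onto
  `[0, 2√(a/c)]` so the curve's interior maximum at `√(a/c)` is reachable at
  mid-range productivity.

The two non-linear K stacks are rescaled so their grand total ΣK (all cells
and slices) equals the linear stack's, which makes population totals
comparable across relationships. The published description leaves the input
scale of the two non-linear formulas open (raw NPP units would make their
shape terms numerically irrelevant); the normalization above is this
package's resolution of that ambiguity, and the curves are exposed
(`qydCurve()`) so alternative conventions can be tested. Each generation K
is Poisson-resampled per cell, which injects the intended spatio-temporal
uncertainty and also lets carrying-capacity ratios fluctuate across 1 —
without this, cells at local K minima could never receive gradient-driven
migrants.

**Neighbour migration.** A focal cell considers its eight neighbours in the
order NW, N, NE, W, E, SW, S, SE. Emigration toward a neighbour requires
(i) a "budding-off" condition — N/K exceeding a uniform threshold drawn once
per focal cell per generation on (0.3, 0.7) — and (ii) a better neighbour,
`K_rel = K_focal/K_nbr < 1`, and then fires with probability
`exp(−3.2 K_rel)`. The migrating group is a beta-resampled proportion
centred on 1/3 (CV 0.05) of the people *remaining* in the source as the
eight directions are processed sequentially; the group is scaled by the
source cell's ruggedness factor and stochastically rounded. Movement is
push-only: a neighbour's immigration is realized by the focal cell's
emigration pass, which reproduces the symmetric published phrasing without
double-counting flows. Both movement passes conserve total population
exactly, by construction and by test.

**Long-distance dispersal.** Each occupied cell meeting the fission
condition attempts one event per generation. The dispersal scale is the
allometric maximum natal dispersal distance `a M^b` (3.31 ± 1.17,
0.65 ± 0.05, M = 50 kg → 22.4–69.3 km, central 42.1 km), inflated 12.7-fold
per tenfold decrease in relative NPP (drier, less productive country forces
wider foraging), and capped at 10 cell-widths (the cap binds after the
productivity inflation). A distance is drawn from the exponential exceedance
law `Pr(d ≥ x) = exp(−x/scale)` and Poisson-resampled into integer axis
displacements with random signs. The event is accepted with the
water-limited probability evaluated at the realized distance and the target
cell's distance-to-water.

**Water limitation.** As printed, `P_l = 1 − (D_l/D_H2O)^Ω` *decreases*
resistance in the driest cells, contradicting its stated purpose of
restricting movement only in arid country. The package default therefore
inverts the ratio — `P_l = 1 − (D_H2O/D_l)^Ω`, clamped to [0, 1], so
acceptance is certain when water is in the target cell and impossible when
the distance to water reaches the dispersal distance itself — and the
literal form remains selectable (`waterLiteral = TRUE`).

**Ruggedness.** The topographic ruggedness index (RMS of the eight
neighbour elevation differences) is min–max standardized once over the
union of land across slices (the published text does not say whether
standardization is per-slice; a static standardization keeps the movement
cost of a given terrain constant through time). The movement reduction
`1 − (a + b G_rel^{1/3})` with `a = 1.001116`, `b = −0.0104453` is at most
~0.93 % at `G_rel = 1`, scaled by the resistance modifier R.

**Catastrophes.** Each generation a Thomas cluster process strikes occupied
cells: Poisson parents uniform over the grid with intensity linear in the
occupied fraction between 0.3 and 1.2, Gaussian offspring displacement
(SD 0.015 of the grid dimension per axis), mean offspring per parent 0.6 ×
the mean dimension of the occupied bounding box. The published intensity
units are under-specified, so the parent intensity carries a calibration
constant fitted once by bisection on the simulated strike rate such that the
long-run fraction of occupied cells struck per generation is 0.14; parents
are placed over the whole grid (not the occupied extent) so the per-cell
strike rate does not depend on how far the population has spread. Struck
cells lose a beta-drawn proportion with mean 0.5 and SD 0.05 (moment
matching gives shape parameters 49.5, 49.5). Cells with fewer than 100
people additionally lose a beta-resampled proportion centred on 0.2
(SD 0.02, mirroring the catastrophe convention; no SD is stated for it).

**Step order and bookkeeping.** One generation applies: K refresh → growth →
neighbour exchange → long-distance dispersal → catastrophes → MVP penalty →
relocation of occupants of newly drowned (or zero-K) cells to the nearest
land → first-arrival recording. The governing equation couples growth and
migration in a single line without an operational order; the order above is
this package's choice. A cell counts as first occupied when it reaches
`N_first = 100` people; saturation is the generation at which every land
cell of the then-current mask has been occupied at least once.

## 2. Scenarios and ranking

A scenario is (entry age ∈ {85, …, 50} ka × entry sequence ∈ {S, N,
simultaneous, S-then-N, N-then-S with a 72-generation ≈ 2000-yr lag} ×
K-relationship), 120 combinations in all; founding groups of 1300–1500
people are seeded in a single event (the published "< 700 yr" entry window
is exposed as an option, not spread over generations). Ensembles run 100
iterations by default with per-iteration seeds derived from the master seed,
and aggregate per-cell mean and 2.5/97.5-percentile arrival maps.

Ranking converts model arrival (generations) to years BP
(`entry age − t · g`), computes Spearman's ρ against the corrected
archaeological surface over the cells defined in both maps (mid-ranked
ties), and reports each scenario's relative change
`Δρ = (ρ − ρ_top)/|ρ_top|` plus marginal means ± SE per factor, holding the
other factors at all their levels. ρ is computed on the ensemble mean map;
correlating per-iteration maps and averaging is a documented alternative the
interface allows.

## 3. The arrival-surface estimator

Given records `(x_i, a_i, σ_i)`, the estimator assumes dates accumulate
uniformly between a reference age `A_0` (default: the youngest record) and
the local arrival age, and that their spatial mean field is stationary:

1. **Variogram.** Binned empirical semivariances over great-circle distance
   are fitted by weighted least squares (weights = pair counts). The fit
   profiles the range parameter over a logarithmic grid and solves a
   non-negative linear system for nugget and partial sill at each candidate.
   A joint quasi-Newton fit proved unreliable here: with taphonomic noise in
   the nugget-dominated regime it converges to a near-zero range that
   behaves as a pure-nugget model and flattens the kriged surface; the
   profiled fit does not have that failure mode.
2. **Ordinary kriging.** Weights solve the standard semivariance system
   with a Lagrange multiplier enforcing Σw = 1; the system is solved on the
   sill-normalized scale for conditioning, with a small diagonal ridge (and
   a message) if it is still singular. With zero nugget the predictor
   interpolates the records exactly.
3. **Preliminary surface.** Under uniform deposition the expected age is the
   midpoint of `[A_0, A]`, so `Â_p(x) = 2M̂(x) − A_0`. The pointwise
   (non-spatial) analogue, `Â = A_0 + (n+1)/n max(a_i − A_0)`, is exposed as
   `solowTerminal()`.
4. **Bias correction.** Treating `Â_p` as truth, k = 100 replicate datasets
   are drawn uniformly on `[A_0, Â_p(x_i)]` at the same locations (plus
   independent Gaussian dating errors σ_i when enabled), the pipeline is
   re-run per replicate (variogram refit included), and the mean replicate
   bias is subtracted: `Â = Â_p − B̂`. The per-cell SD over replicates is
   the reported uncertainty; estimates are floored at `A_0`.

Records can be filtered by quality rating allow-list and by site-name
exclusion (for single-site sensitivity reanalyses).

**Identifiability.** The age of one record carries the taphonomic noise of
its whole sampling window (variance `(A − A_0)²/12`). The spatial signal is
only recoverable when the arrival surface varies by more than a typical
window length across the map — otherwise the empirical variogram is flat at
any sample size and every estimate collapses to the global mean. The
synthetic validation therefore plants a slow front (0.25 km yr⁻¹ over a
continent-sized domain, spanning ≈ 18,000 yr of arrival ages): an
identifiability condition of the experiment, not a tuning of the estimator.
On that design the corrected surface achieves rank agreement ≈ 0.6 with the
planted truth at n = 150 records (≈ 0.9 at n = 400), and roughly halves the
mean absolute error of naive kriging of the raw ages.

## 4. Sensitivity analysis

`latinHypercube()` stratifies 12 parameters over their published ranges
(growth rate 0.10–0.31; minimum allometric dispersal 11–34 km; dispersal cap
modifier 1–5×; MVP size 50–150 and penalty 0.1–0.3; hydrological resistance
1.5–4.5; catastrophe mortality 0.38–0.99; migrating proportion 0.17–0.50;
fission bounds 0.15–0.45 and 0.35–0.99; ruggedness modifier 0.5–1.5;
occupancy threshold 50–150). Each design row runs one simulation; the
response is years to continental saturation, with non-saturating runs
flagged censored (the horizon is a lower bound) and excluded from emulation.
Because the two fission bounds are sampled independently over overlapping
ranges, an inverted pair is reordered rather than rejected. The emulator is
gradient-boosted regression trees with the published settings (Gaussian
loss, bag fraction 0.75, learning rate 0.008, depth-2 trees for first-order
interactions, up to 10,000 trees, stopping when the training-RMSE
improvement falls below 10⁻⁴), and relative influence is the normalized
split-gain share, summing to 100. The emulator's deviance explained is
reported but no target value is asserted for it on synthetic landscapes.

A reproducible directional result on the synthetic continent: a larger
migrating proportion accelerates saturation (negative effect on time), in
line with the reported influence direction. The reported *negative*
direction for catastrophe severity does **not** reproduce here: in this
implementation harsher catastrophes monotonically delay saturation (severity
0.9 prevents it within 500 generations on the test landscape), which is the
mechanistically expected sign; the discrepancy is documented rather than
forced.

## 5. The synthetic data generators

`makeLandscape()` emulates the structure the model needs, not any real
geography: a smooth elevation field rank-mapped so a chosen fraction of
cells forms a continental shelf between −120 m and 0 m (default 15 %, deep
sea 38 %); a monotone sea-level fall (−75 → −95 m) so the shelf emerges
through the run; a single connected landmass (stray islands are sunk: saturation is well
defined on a connected continent, whereas archipelago fragments beyond the
10-cell dispersal cap would make it structurally impossible); an elliptical
interior lake basin with a falling level series; NPP drifting linearly
between two autocorrelated fields within 0.02–1.4 kg C m⁻² yr⁻¹ (magnitudes
chosen so per-cell K spans the ≈ 55–3548 people-per-cell range implied by
the density bounds); and
distance-to-water as the distance transform of a thresholded smooth field
(10 % wet cells). Fields are white noise convolved with a Gaussian kernel;
the `corLength` parameter is the lag at which the correlogram falls to 1/e
(default 8 cells ≈ 450 km, a mesoscale climate-field roughness).

What the generator does *not* emulate: real coastline geometry, covariation
of NPP with elevation or with water availability, temporally correlated
sea-level oscillations, and the empirical clustering/quality structure of
real date compilations. Passing tests on synthetic data therefore
demonstrate internal correctness and estimator consistency — not that the
model's ecological parameters are right for any real continent.

`makeDates()` places sites with configurable spatial clustering (cluster
centres uniform over eligible cells, Gaussian-jittered members, sites
scattered within their cell), draws ages uniformly on `[A_0, A(x_i)]`, and
attaches dating SDs (100–800 yr), optionally added as Gaussian error.

## 6. Numerical choices, degenerate inputs, limitations

* Stochastic rounding everywhere people are moved or killed; transfers are
  debited/credited in integers, so movement conserves ΣN exactly.
* Beta draws are moment-matched from (mean, SD); SDs too large for a beta
  fall back to the mean deterministically.
* `K = 0` with `N > 0` (drowned or sterile cells) triggers relocation to the
  nearest land cell rather than silent immortality; a fully drowned world
  loses its population.
* Constant NPP makes the min–max rescale undefined and errors; an all-equal
  elevation field returns zero ruggedness rather than 0/0.
* The simulation horizon defaults to 300 generations (the published
  reporting point); on the default synthetic continent full saturation
  typically needs longer because arid pockets admit only rare long-distance
  jumps, so saturation-dependent analyses in the tests use a wetter,
  smaller landscape (40 × 40, 55 % wet cells) where it occurs in ~250–400
  generations.
* Kriging is global (the record sets are small); local-neighbourhood kriging
  is out of scope.
* Entry cells are snapped to the nearest land cell of the entry-age mask;
  no canonical coordinates exist for the two entry regions.
* The per-iteration problem sizes used throughout the tests (86 × 87
  landscape, 20-iteration ensembles, k = 100 replicates, 300-row designs)
  were chosen to exercise the full pipeline at the model's native grid scale
  while keeping a complete validation run in minutes on one core.
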