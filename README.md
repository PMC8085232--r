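# paleospread

Stochastic cellular-automaton modelling of human dispersal across a
palaeo-landscape, with a spatially explicit bias-correction estimator for
sparse archaeological dates.

## The problem

When anatomically modern humans colonised a new continent, where did they
enter, when, and how fast did they spread? Archaeological dates are too
sparse, too unevenly sampled and too noisy to answer this directly: the
oldest date at a site systematically *under*-estimates first arrival
(the Signor–Lipps effect — datable material accumulates only after people
arrive and is progressively lost with age), and site coverage is strongly
spatially biased. `paleospread` addresses both sides of the problem for
researchers in archaeology, palaeoecology and human biogeography:

1. **A forward model.** A fully stochastic cellular automaton on a
   0.5° × 0.5° grid (86 × 87 cells by default) in which each cell's
   population follows Ricker dynamics against a carrying capacity derived
   from hindcasted net primary production, people migrate to neighbouring
   cells up carrying-capacity gradients, occasionally leap long distances
   (limited by water availability and terrain ruggedness), and suffer
   spatially clustered catastrophic mortality.
2. **An inverse estimator.** An arrival-surface estimator that turns a table
   of dated records into a bias-corrected map of first arrival: ordinary
   kriging of the ages, a Solow-type terminal-date correction under the
   uniform-deposition taphonomic model, and a simulation-based spatial bias
   removal with optional Gaussian dating-error integration.
3. **Scenario ranking and sensitivity analysis.** Spearman rank agreement
   between simulated first-arrival maps and the corrected archaeological
   surface ranks competing entry scenarios; a 12-parameter Latin-hypercube
   design with a boosted-regression-tree emulator attributes the model's
   output variance to its parameters.

## The model in brief

Per generation (1 g = 27.9 yr) and cell (i, j), abundance follows

    N[i,j,t+1] = N[i,j,t] · exp( r_m (1 − N[i,j,t] / K[i,j,t]) ) − (E[i,j,t] − I[i,j,t])

where K is carrying capacity (Poisson-resampled each generation) obtained by
rescaling net primary production `P_p` onto hunter-gatherer density bounds
(0.018–1.152 people km⁻², times the 3080.25 km² cell area) through one of
three relationships — linear, rotated parabolic (`K = a(P_p − h)² + K_max`),
or reciprocal quadratic yield density (`K = P_p / (a + b P_p + c P_p²)`) —
and E/I are emigration and immigration. Neighbour emigration fires when a
cell exceeds a uniform 30–70 % fission threshold of N/K and the neighbour is
better (`K_rel < 1`), with probability `exp(−3.2 K_rel)`; migrating groups
are a beta-resampled third of the remaining population. Long-distance
dispersal follows the exponential exceedance law `Pr(d) = exp(−d / aM^b)`
around the allometric maximum natal dispersal distance (22.4–69.3 km for a
50 kg human), inflated 12.7-fold per tenfold drop in relative productivity,
and accepted with the water-limited probability
`P_l = 1 − (D_H2O / D_l)^Ω`. Cells below 100 people suffer an extra
beta-resampled 20 % mortality (minimum-viable-population penalty), and a
calibrated Thomas cluster process strikes ~14 % of occupied cells per
generation with beta-distributed ~50 % mortality.

The inverse estimator knits Eqs. of the kriging system
(`M̂(x) = Σ w_i a_i`, weights summing to one via a Lagrange multiplier),
the Solow correction (`Â = A_0 + (n+1)/n · max(a_i − A_0)`), the
stationary-field preliminary surface (`Â_p = 2M̂ − A_0`) and a
Cook–Stefanski-style replicate bias removal
(`Â = Â_p − B̂`, `B̂ = mean_k Â_p^(k) − Â_p`).

All inputs can be synthetic: `makeLandscape()` generates a connected
continent with a drowned shelf, a monotone sea-level curve, autocorrelated
NPP and a distance-to-water layer; `makeDates()` samples clustered dated
records from a planted arrival surface under uniform taphonomic thinning.

## Worked example

```r
library(paleospread)

landscape <- makeLandscape(seed = 7)   # synthetic 86 x 87 continent
landscape
#> PaleoLandscape: 86 x 87 cells, 46 time slices
#>   ages: 85000 .. 40000 yr BP
#>   land cells (oldest slice): 3889

entry <- nearestLandCell(landscape, 50000, c(25, 5))  # west-coast entry
scn <- scenario(entryAgeKa = 50, sequence = "S", kModel = "parabolic")
ens <- runScenario(scn, landscape, entryCells = list(S = entry),
                   nIter = 5, seed = 42, horizon = 300)
ens
#> EnsembleResult: S_50_parabolic | 5 iterations
#>   cells reached (any iteration): 3623
#>   saturation: never reached
mean(ens@trajectories[300, ]) / 1e6
#> [1] 2.45
```

Five replicates of a 50-ka single southern entry fill 3623 of the continent's
cells within 300 generations and carry about 2.45 million people at the
horizon; the median cell is first occupied (≥ 100 people) around generation
180. Full saturation does not occur within 300 generations here because the
synthetic interior holds arid pockets (large distance-to-water) that the
water-limited dispersal only rarely crosses — the same interior gap the
model produces on the real continent.

The inverse estimator, validated against a planted truth:

```r
spec <- gridSpec()
mask <- landMaskAt(landscape, 50000)
truth <- makeArrivalTruth(spec, mask, entry, 50000)  # planted arrival surface
truth[truth < 32000] <- NA
dates <- makeDates(truth, spec, n = 150, A0 = 30000, seed = 5)
set.seed(1)
surf <- biasCorrectedSurface(dates, spec, !is.na(truth), A0 = 30000, k = 100,
                             useSigma = FALSE)
surf
#> ArrivalSurface: 4055 cells, 100 replicates, A0 = 30000 yr BP
#>   corrected ages: 30903 - 45552 yr BP
spearmanMapCorrelation(arrivalEstimate(surf), truth)
#> [1] 0.61
```

From 150 uniformly thinned, spatially clustered dates the corrected surface
recovers the planted arrival field with rank agreement 0.61, and its mean
absolute error (about 2500 yr) is less than half that of naively kriging the
raw ages (about 5400 yr — the kriged mean estimates deposition time, not
arrival).

`scoreEnsemble()` + `rankScenarios()` then reproduce the scenario-ranking
workflow, and `latinHypercube()` → `runDesign()` → `emulateInfluence()` the
global sensitivity analysis. A thin command-line wrapper for the main
workflows is in `inst/scripts/paleospread-cli.R`.

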