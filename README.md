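# isoweb

Stable-isotope food-web analysis for coastal ecosystems: who eats whom, in
what proportion, and how that changes along environmental gradients.

`isoweb` is aimed at trophic ecologists working with bulk δ13C/δ15N
measurements from community surveys — the setting where a few hundred
consumers across many functional groups, a handful of basal sources (POM,
SOM, phytoplankton, macroalgae), and a station grid along a depth gradient
must be turned into a quantitative picture of benthic–pelagic coupling.

## What it implements

**Preprocessing.** δ-notation arithmetic; lipid normalization of δ13C for
samples with C:N > 3.5 (`δ13C − 3.32 + 0.99·C:N`); spatial baseline
correction `δX − δX_local + δX_mean` against a filter-feeding primary
consumer; trophic levels `TL = 2 + (δ15N − δ15N_base)/3.4`; and a scaled
nitrogen trophic enrichment factor `Δ15N = 5.92 − 0.27·δ15N_consumer`
(carbon TEF 1.0 ± 0.4 ‰).

**Bayesian mixing model.** For diet proportions `p` on the K-simplex, each
consumer's isotope pair follows

    y_j ~ N( Σ_k p_k (μ_kj + Δ_kj),  Σ_k p_k²(σ_kj² + τ_kj²) + σ_res,j² )

with a Dirichlet(1,…,1) prior and half-Cauchy residual SDs. Sampling is
adaptive random-walk Metropolis on ILR-transformed proportions; convergence
is gated on R-hat ≤ 1.1 and Geweke |z| ≤ 2 per proportion. Posterior
correlation drives source merging (|r| > 0.5 plus declared ecological
similarity, moment-matched pooling), and per-group posteriors assemble into
a consumer-by-prey diet matrix masked by stomach-content topology.

**Diet along depth.** A continuous-covariate extension models
`p_i = ilr⁻¹(α + β·depth_i)` (depth standardized internally), yielding
diet-vs-depth curves with 95% bands.

**Environmental smooths.** Penalized additive regression of isotope values
on Depth, SsTemp, BotTemp, Salinity and Chl-a: cubic regression splines,
GCV-chosen smoothing, and exhaustive AICc subset selection capped at four
variables.

**Simulator.** `scenario()`/`simulate_consumers()` forward-simulate surveys
from the mixing likelihood itself with known diets, optional ILR-linear
depth trends and per-station baseline gradients, so every stage is testable
against ground truth.

## Worked example

Reconstruct the diet of benthic suspension feeders (filter-feeding
bivalves) from published Beibu Gulf group summaries — source means/SDs and
the consumer's mean ± SD — with the scaled nitrogen TEF:

```r
library(isoweb)

prob <- group_mixing_problem(
  consumer = "Benthic suspension feeder",
  sources  = c("SOM", "POM", "Phytoplankton"),
  seed = 1
)
fit <- fit_mixture(prob, chains = 4, iter = 20000, burn = 10000,
                   thin = 10, seed = 1)
fit
#> Bayesian mixing model posterior (4 chains, 1000 kept draws each)
#>          source   mean     sd rhat
#> 1           SOM 0.0162 0.0164    1
#> 2           POM 0.0198 0.0195    1
#> 3 Phytoplankton 0.9640 0.0253    1
```

Phytoplankton dominates the bivalves' diet (posterior mean ≈ 0.96, i.e.
~96% of assimilated carbon/nitrogen), with SOM and POM marginal — the
pattern expected for filter feeders sitting directly on pelagic primary
production. R-hat ≈ 1.00 means the four chains agree.

Trophic levels from the same summary table:

```r
tb <- beibu_groups()
cons <- tb[tb$role == "consumer", ]
base <- solve_baseline_d15n(cons$d15n_mean, cons$tl_mean)
base
#> [1] 9.117077
trophic_level(14.74, base)   # piscivorous fish
#> [1] 3.653801
```

The numbered scripts under `analysis/` run the full study battery —
simulation, trophic levels, diet mixing, depth-covariate curves, GAM
selection, and the end-to-end pipeline — writing their tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_trophic_levels.R
# ... through 06_pipeline.R
```

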