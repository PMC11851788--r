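---
title: "Models and methods behind isoweb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind isoweb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoweb)
```

isoweb reconstructs trophic structure in coastal food webs from bulk
δ13C/δ15N measurements: who eats whom and in what proportion, how diets
drift along a depth gradient, and which environmental variables shape the
isotopic landscape. This vignette records the models, the assumptions they
make, the numerical choices, and what the packaged simulations can and
cannot demonstrate.

## Isotope preprocessing

All isotope values are per-mil (‰) deviations from the international
standards (PDB for carbon, atmospheric N2 for nitrogen); `delta_from_ratio()`
and `ratio_from_delta()` implement the δ map and its inverse. Two
corrections precede any modelling, in this order (lipid first, then
baseline; the order is configurable by calling the functions directly but
the pipeline fixes it):

* **Lipid normalization** (`lipid_correct()`): lipid-rich tissue is depleted
  in 13C. With the elemental C:N ratio as a lipid proxy, samples with
  C:N strictly above 3.5 are corrected by `δ13C − 3.32 + 0.99 × C:N`;
  equality at 3.5 is deliberately untouched.
* **Spatial baseline correction** (`baseline_correct()`,
  `compute_baselines()`): the isotopic baseline drifts along the
  nearshore–offshore gradient. Each consumer value is shifted by
  `− local baseline + study-mean baseline`, using a long-lived filter-feeding
  primary consumer as baseline. Stations without baseline samples borrow the
  nearest sampled station by depth (logged); this nearest-by-depth rule is a
  package choice where the original spatial model is unspecified.

Trophic level uses the classic baseline formulation
`TL = 2 + (δ15N − δ15N_base)/3.4` (`trophic_level()`), with the baseline
bivalve anchored at TL 2 and a constant 3.4 ‰ per-step enrichment. The
mixing models instead use a *scaled* nitrogen trophic enrichment factor,
`Δ15N = 5.92 − 0.27 × δ15N_consumer` (`proportional_tef()`), which shrinks
as consumers climb the food chain; carbon TEF is 1.0 ± 0.4 ‰. Keeping
3.4 ‰ in the TL equation while the mixing model uses the scaled TEF is
intentional and mirrors standard practice: the TL formula is a convention
anchored to published baselines, while the TEF entering the likelihood
should be the best available estimate for the study system. Group
summaries use the sample (n−1) SD everywhere; single-member groups report
`sd = 0` and are flagged rather than dropped.

## The mixing model

For a consumer group with K candidate sources, diet proportions `p` live on
the simplex and each individual's isotope pair is modelled as

y_j ~ Normal( Σ_k p_k (μ_kj + Δ_kj),  Σ_k p_k² (σ_kj² + τ_kj²) + σ_res,j² )

per isotope j, where (μ, σ) are source moments and (Δ, τ) TEF moments. The
prior is Dirichlet(1, …, 1). The per-isotope residual SD σ_res has a
half-Cauchy(0, 2 ‰) prior — weakly informative on the δ scale — and can be
switched off (`residual_error = FALSE`), in which case the posterior is a
density over `p` alone and can be checked against brute-force simplex-grid
quadrature. The residual term matters in practice: real consumers often sit
outside the TEF-shifted source hull in one isotope (the benthic suspension
feeders here are an example in carbon), and without it the model has no
probability mass to give such data.

Sampling is random-walk Metropolis on ILR-transformed proportions (plus log
residual SDs), an unconstrained space, with the ILR Jacobian included in
the target. The proposal adapts during burn-in only — a global scale
steered toward ~30% acceptance, and a Haario-style empirical-covariance
update that aligns proposals with the posterior's principal directions —
then freezes, so the kept draws come from a fixed kernel. The covariance
adaptation matters: with two isotopes and K = 4 sources the mean constraint
identifies only a one-dimensional ridge of proportions, and an isotropic
walk mixes along that ridge far too slowly. Four chains with overdispersed
starts are the default. Because the Gaussian likelihood
depends on the data only through per-isotope sufficient statistics
(n, mean, sum of squares), each iteration costs O(K) and the reference
settings (4 × 20,000 iterations) run in seconds; tests use shorter chains
with the same convergence gate.

**Convergence** is assessed per proportion with split R-hat
(`gelman_rubin()`) and Geweke scores (`geweke()`, AR-spectrum standard
errors, 10%/50% windows). Per-chain Geweke z's are combined across chains
by Stouffer's rule (Σz/√C) so the gate tests one calibrated score per
parameter; taking the maximum across chains would alarm on perfectly mixed
chains. The gate is R-hat ≤ 1.1 and |z| ≤ 2; failures set
`converged = FALSE` and warn — results are flagged, never silently dropped.

**Source merging** (`merge_sources()`): when two sources' posterior
proportions correlate beyond |r| > 0.5 (strictly) *and* the caller declares
them ecologically similar, they are merged (union–find handles chains) and
the model must be rerun. Combined moments are moment-matched pooling —
mean of member means; variance = mean of variances + variance of means —
and merged members' Dirichlet concentrations add, which is exactly the
aggregation property of the Dirichlet prior.

**Replication from printed summaries.** `group_mixing_problem()` rebuilds a
consumer's mixing problem from a published group-summary table. Simulated
consumers are moment-matched: after drawing n individuals from the printed
mean/SD they are affinely rescaled so the sample mean and SD equal the
printed values exactly. The likelihood above depends on data only through
those moments, so this reconstructs the likelihood the original analysis
saw instead of a noisy resample (with n as small as 14, raw resampling
moves posterior means by ±0.1 purely through the simulation seed).

## Diet along the depth gradient

`covariate_problem()` / `fit_covariate_mixture()` let proportions vary with
a continuous covariate (depth) through a linear model on ILR coordinates:
`p_i = ilr⁻¹(α + β x_i)`, with depth standardized to mean 0, SD 1
internally, and Normal(0, 1) priors on α and β on that scale. Curves
reported by `diet_curves()` are invariant to the standardization constants
(verified by refit in the tests); coefficients are basis-dependent, and the
Helmert-type ILR basis is fixed and recorded. There are no random station
effects — the covariate enters as a fixed effect only — and no
multi-covariate mixing models. Crossover/inflection depths are read
descriptively off the posterior-mean curves, not tested formally.

## Additive smooths of isotopes on environment

`fit_additive()` regresses an isotope on environmental variables as a sum
of cubic-regression-spline smooths (basis and curvature penalty from
mgcv's `smoothCon`; k = 10 per smooth by default), fitted by penalized
least squares with identity link. Per-term smoothing parameters minimize
GCV = n·RSS/(n − tr(H))² by coordinate descent over a log10 λ grid from −4
to 4 in 0.25 steps, two sweeps — a deliberately simple, reproducible
search; the tests verify the selected λ's are local minima on that grid
and that single-smooth fits match mgcv's own GCV fits closely. AICc uses
the Gaussian log-likelihood with tr(H)+1 parameters. Per-term F tests are
Wald-type approximations on n − tr(H) residual degrees of freedom and are
labelled as such. `select_model()` fits every non-empty subset of
candidates up to four terms (30 models for five candidates) and ranks by
AICc, breaking ties toward fewer terms, then lower GCV. Published
real-data fit statistics are not reproduction targets — the underlying
data are not deposited — so this module's guarantees are property-based
(OLS equivalence on linear signals, driver recovery on synthetic
gradients).

## The simulator and what passing tests mean

`scenario()` / `simulate_consumers()` draw consumers from exactly the
mixing likelihood above (source and TEF uncertainty enter the variance as
Σp²(σ²+τ²) rather than resampling a source value per individual), so
estimator and generator are conjugate and recovery tests probe the
estimator, not a model mismatch. Stations are evenly spaced over 10–90 m
(24 by default, matching a typical survey of this kind); temperatures fall
and salinity rises monotonically with depth, chlorophyll-a decays
exponentially, all with seeded noise. Each group draws from its own seed
substream, so adding a group never perturbs another's data. Baseline
drift is imposed as arbitrary per-station offsets — no spatial
autocorrelation model, no seasonality.

The headline recovery study (four sources, 100 consumers, 50 replicates)
draws the true diet from the Dirichlet prior in every replicate and
simulates from the exactly matching likelihood. That is deliberate: under
partial identification the frequentist coverage of Bayesian intervals at
one fixed truth is not a guaranteed property of a correct implementation,
whereas prior-drawn truth makes 95% coverage an exact consequence of
correctness — so a coverage failure in that design always indicts the
code, not the test.

Consequently, passing recovery tests show the machinery is correct and
calibrated *under its own assumptions*. They do not show that real
consumers obey a Gaussian mixing model with linear-in-ILR depth trends,
that TEFs are known, or that sources are exhaustive — the usual caveats of
isotope mixing apply. With two isotopes and K > 3 sources the proportions
are only partially identified; posteriors then lean on the Dirichlet prior
along the unidentified ridge, which is why merging confounded sources is
part of the workflow rather than an afterthought.

## Problem sizes and defaults

Reference MCMC settings are 4 chains × 20,000 iterations (half burn-in,
thin 10) for the summary-level reconstructions; simulation studies in the
test suite use 2–4 chains × 3,000–10,000 iterations with the same
convergence gate, and recovery studies use 30–50 seeded replicates at
n = 100 consumers — sizes chosen so the full study battery re-runs comfortably on
a laptop while keeping Monte-Carlo error well below the tolerances being
asserted. The GAM selection studies use n = 200 observations and 2:1
signal-to-noise, a regime comparable to the per-group sample sizes the
package targets.

## Known limitations

* No concentration-dependence or elemental-assimilation weighting in the
  mixing model; no informative priors from stomach contents (stomach data
  enter only through the topology).
* Trophic topology is always user-supplied at the species→group level;
  the package does not infer links.
* The Geweke spectral estimate uses an AR fit; on very short chains
  (< 100 kept draws per window) its standard errors are rough.
* The additive models are Gaussian identity-link only, with no tensor
  interactions or spatial smooths.
* AICc ranking over all subsets is not selection-consistent: with several
  irrelevant candidates, a spurious extra smooth wins the ranking a
  substantial fraction of the time through chance-level AICc gains — a
  property of AIC-family criteria generally (mgcv's own GCV/AICc pipeline
  behaves identically on the same data), independent of sample size and
  signal-to-noise ratio. The true driver is reliably *contained* in the
  winning model; trimming it to the minimal model needs a
  parsimony-forcing criterion (e.g. preferring the smallest model within
  a small AICc band), which `select_model()`'s ranking output makes easy
  to apply but which is not imposed by default.
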