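---
title: "From community leaf size to ecosystem productivity: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From community leaf size to ecosystem productivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafprod)
```

## The scientific problem

Leaf size of woody dicots varies systematically with climate: where water
and the energy to evaporate it are both available (high actual
evapotranspiration, AET), selection favours large leaves; in dry or cold
regions it favours small ones. The same climatic axis controls canopy leaf
area and hence ecosystem gross and net primary productivity (GPP, NPP).
Community *mean* leaf size — the unweighted average over the species
present in a grid cell of each species' leaf length, width, or
$\tfrac{2}{3}\,L\,W$ elliptical area proxy — therefore tracks productivity
closely enough to act as a *transfer function*: a statistical mapping from
a trait that fossilises well to a flux that does not, usable for
reconstructing palaeo-productivity from fossil leaf assemblages.

`leafprod` implements that whole inference chain as tested code: gridding
and community-mean construction, candidate trait–climate model families,
spatially corrected significance tests, variance partitioning,
inverse-logistic transfer functions with cross-region validation,
phylogenetic signal, and piecewise structural equation models — plus a
synthetic-data generator that produces inputs with exactly the statistical
structure the analysis presumes, so every stage is testable without any
external download.

## The central model

The forward trait–climate model is the three-parameter logistic

$$y = \frac{K}{1 + e^{\alpha - r x}},$$

with $K$ the upper asymptote (units of the response), $\alpha$
dimensionless and $r$ a rate per predictor unit. Solved for the predictor,
the same triple gives the inverse-logistic transfer function

$$y = \frac{1}{r}\left(\alpha - \ln\left(\frac{K}{x} - 1\right)\right),
  \qquad 0 < x < K,$$

which maps community mean leaf size $x$ to productivity $y$. Its accuracy
metrics are the standard error of estimate
$SE = \sqrt{\sum (y_\mathrm{est} - y_\mathrm{real})^2 / (n-1)}$ and its
percentage of the observed range,
$SE\% = 100\,SE / (\max y_\mathrm{real} - \min y_\mathrm{real})$.

### Fitting the inverse logistic

Conditional on $K$, the transfer function is *linear* in
$(\alpha/r,\,1/r)$ with regressor $\ln(K/x - 1)$. We therefore fit by
profiling: an exact inner OLS nested in a one-dimensional least-squares
search over $K$ (`optimize`, tolerance $10^{-9}$), with $K$ bounded below
by $\max(x)(1+10^{-6})$ so the logarithm stays defined. This is more
robust than a three-parameter descent — there is nothing to mis-converge —
and recovers generating parameters to $\sim 10^{-9}$ relative error on
noiseless data. If the profile optimum presses against the lower bound,
the single largest-trait cell is excluded and the model refitted (at most
5 rounds), which is how usable-cell counts can differ between trait
measures. Predictions outside $(0, K)$ are returned as `NA` with a count —
never clamped to the asymptote, because a clamped prediction would
silently fabricate saturation.

The forward logistic (`fit_model(..., "logistic")`) retains a genuine
three-parameter Levenberg–Marquardt fit (via `minpack.lm`), warm-started
from the log-linearisation at $K_0$ set to 1.05, 1.5 and 3 times
$\max(y)$; the best final SSE wins. Convergence: relative SSE change
$<10^{-10}$ or 500 iterations. The linear families are plain OLS;
`sqrt_linear` reports $R^2$ on the square-root scale and is flagged
accordingly. $R^2$ is otherwise always computed on the raw response — the
natural default when comparing nested and non-nested families.

## The synthetic generator: what it emulates

The generator's defaults *are* the study conditions every test and the
acceptance analyses run under:

* **Climate fields.** Gaussian random fields with exponential covariance
  $C(d) = \sigma^2 e^{-d/\rho}$ on the 50-km cell centres, simulated by
  exact Cholesky factorisation (correct at desk scale, $\lesssim 5000$
  cells; an FFT simulator is the documented upgrade path). Defaults: MAT
  $\mathcal N(10, 8^2)$ °C, MAP $\mathcal N(800, 350^2)$ mm (floored at 1
  mm), ranges 400 km. Potential evapotranspiration is an energy proxy
  $58.93 \cdot \max(\mathrm{MAT}, 0.5)$ mm (a Holdridge-style
  biotemperature scaling), and AET is the smooth minimum
  $\mathrm{MAP}\cdot\mathrm{PET}/(\mathrm{MAP}+\mathrm{PET})$, so AET
  correlates with both water and energy; AI = MAP/PET. Warm/cold quarter
  temperatures are MAT $\pm$ 8 °C with small perturbations; three soil
  variables share one spatial driver so their PC1 carries well over 70% of
  edaphic variance.
* **Species pool.** Median leaf length is log-normal
  ($\mu = \log 6$ cm, $\sigma = 0.55$), truncated by inverse-CDF below
  92% of the transfer asymptotes so community means stay strictly inside
  the transfer domain; the flora "range" is a symmetric ±20–60% band
  around the median, so the midpoint convention recovers the median
  exactly. Width is length times a log-normal ratio (mean 0.45). Each
  species' AET niche optimum is the *inverse* of the forward trait
  logistic evaluated at its median length, plus $\mathcal N(0, 60)$ mm
  noise — a monotone size–niche coupling that makes the community mean
  trait follow, approximately, the forward logistic in AET. Setting
  `niche_coupling = 0` severs the link (the decoupled null).
* **Ranges.** Presence is Bernoulli with Gaussian niche weight
  $\exp(-(AET - o)^2 / 2b^2)$, breadth $b = 120$ mm. Sampling (rather
  than thresholding) produces realistic richness gradients; low-richness
  cells are *not* patched in the generator — the downstream $\geq 20$
  species filter has to do its documented job. Every species is
  guaranteed at least one cell (resampling, then deterministic placement
  at its best cell).
* **Productivity.** GPP and NPP are generated from one driver trait's
  community mean by the inverse-logistic form with the six (K, α, r)
  triples of `default_transfer_params()`, plus additive Gaussian noise
  with sd equal to `noise_frac` (default 0.08) of the noiseless range —
  the noise scale at which refitted transfer functions reproduce
  $SE\% \approx 8$–9% and $R^2 \approx 0.74$–0.9. The noise structure
  linking trait and productivity is not identified by the analysis itself;
  additive Gaussian on the productivity scale is an explicit, configurable
  assumption. Noise is deliberately never clamped: truncating it to
  enforce $GPP \ge NPP \ge 0$ would bias every refit the round-trip
  checks rely on, so violations are counted and reported instead, and the
  invariant is enforced by `validate_cell_table()` for observational
  inputs only. Optional 16-year stacks add i.i.d. year effects (5% of
  range) with no temporal autocorrelation — ranked-year means only need
  the ranking. LAI is a monotone noisy logistic of AET.
* **Phylogeny.** An ultrametric birth–death tree (`birth` 0.15, `death`
  0.05 per Myr) with tip traits
  $w\,\mathrm{BM}^* + (1-w)\,\varepsilon$, both components standardised,
  $w$ the signal weight: $w = 1$ is pure Brownian motion (Blomberg's
  $K \approx 1$), $w = 0$ is white noise ($K \approx 0$). The default
  $w = 0.3$ leaves leaf size phylogenetically labile — the regime in
  which the trait–climate story is coherent. Genera/families are
  delimited by cutting the tree at a chosen age; clade ages are *stem*
  ages read from node heights (crown ages behind a flag).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: real floristic composition and range geometry,
projection/CRS effects, abundance structure (community means are
presence/absence-weighted by design), intraspecific trait variation,
temporally autocorrelated productivity anomalies, and any mechanistic
(causal) link between leaf size and carbon flux. The generator encodes the
*correlative* structure the method assumes; recovering its parameters
validates the statistical machinery, not the ecophysiology.

## The supporting statistics

* **Dutilleul's modified t-test.** Correlation tests between
  autocorrelated surfaces use the effective sample size
  $\hat M = 1 + \mathrm{tr}(B\hat\Sigma_A)\,\mathrm{tr}(B\hat\Sigma_B) /
  \mathrm{tr}(B\hat\Sigma_A B \hat\Sigma_B)$ with $B = I - 11^\top/n$,
  and $t = r\sqrt{(\hat M - 2)/(1 - r^2)}$ on $\hat M - 2$ df. The
  spatial correlation matrices come from a correlogram: pairwise
  distances binned into equal-width classes (Sturges' rule on the pair
  count by default; the class count and implicitly the maximum lag are
  configuration, since no canonical choice exists), Moran-type per-class
  estimates, negative values retained, diagonal 1. With identity
  matrices the classical test is recovered *exactly*; $\hat M$ is
  clamped to $(2, n]$ with a flag. On independent range-5 fields on a
  15×15 grid the empirical size at $\alpha = 0.05$ is ~0.04 where the
  naive test rejects at ~0.58.
* **Hierarchical partitioning.** All $2^k - 1$ subset OLS fits; the
  independent effect of predictor $i$ averages its $R^2$ increment over
  hierarchy levels. This equals the Shapley/LMG value (average over all
  $k!$ orderings), which is how the tests cross-check it; the independent
  effects sum exactly to the full-model $R^2$. Limited to $k \le 8$ —
  beyond that it errors rather than approximates.
* **Commonality (Venn) partition.** Unique, pairwise and three-way
  components by inclusion–exclusion over the seven subset $R^2$ values;
  negative components (suppression) are reported as-is; the seven
  components reassemble the full $R^2$ to machine precision.
* **Blomberg's K.** GLS mean $\hat a = (1^\top V^{-1}y)/(1^\top V^{-1}1)$,
  $K = (MSE_0/MSE)$ over its Brownian expectation
  $(\mathrm{tr}(V) - n/\sum_{ij}(V^{-1})_{ij})/(n-1)$. Exactly 1 on a
  star tree, affine-invariant, permutation p-value
  $(1 + \#\{K_\pi \ge K\})/(n_\pi + 1)$ with vectorised permutations.
  Zero-length branches get an $\varepsilon = 10^{-8}$ Myr ridge before
  inversion.
* **Piecewise SEM.** Saturated DAGs only (no d-separation tests — the
  three study topologies are saturated, so fit indices are undefined);
  GPP/NPP square-root transformed before z-standardisation; each
  endogenous node fitted by OLS on its parents; indirect effects are
  exact path products summed over all directed paths. p-values are
  classical OLS t-tests; substituting spatially corrected df per
  component is a possible extension, deliberately off by default so the
  component fits stay interpretable as plain regressions.

## Numerical and design choices

* Cell membership is half-open ($x_0 + is \le x < x_0 + (i+1)s$), indices
  0-based, `cell_id` $= j\,n_x + i$ — fixed conventions so gridding tests
  are bit-exact. Coordinates are planar km; no CRS handling in core.
* "Median per species" from a flora min–max range means the midpoint;
  the maximum-based variant is a flag. The community length–width
  product is the mean over species of species-level products, not the
  product of community means.
* The richness filter keeps the boundary (cells with *fewer than* 20
  species are removed). Ranked-year means break ties by year order.
* The trait–climate correlation matrix applies Bonferroni
  $\alpha = 0.05/48$ (configurable divisor).
* Per-species missing bounds skip the species with a count (mirroring
  real floras' ~93–94% coverage) rather than erroring.
* The transfer table is fitted against the single generated GPP/NPP
  surface by default, so the driver trait's row has the best $R^2$ and
  the other traits' rows are slightly weaker — the pattern real
  compilations show. The `transfer_roundtrip` mode instead fits each of
  the six rows on productivity generated noiselessly from its own trait,
  which is the only configuration in which all six rows can (and do)
  recover their generating parameters exactly; it exists to make the
  zero-noise round trip a sharp test of the full chain.
* All randomness flows from one master seed through fixed per-stage
  substreams; equal seeds give bit-identical outputs, including Newick
  strings.

## Problem sizes

The bundled analyses and tests run at desk scale, chosen as the smallest
sizes at which the statistical checks are sharp: 25×25- to 30×30-cell
grids with 150–400 species for pipeline runs; 2000–3000 cells for
transfer refits; 1000 simulated field pairs (15×15 grid) for the modified
t-test's size; 200 trees of 100 tips for Blomberg's K calibration;
$n = 10^5$ for SEM path recovery. The exact Cholesky GRF simulator is the
binding constraint on grid size.

## Known limitations

* Abundance weighting and intraspecific trait variation are out of scope
  (the community mean is presence/absence-based by design, which is also
  what makes it applicable to fossil assemblages).
* The generator's clade-age structure carries no built-in age × leaf-size
  interaction, so the interaction regression is exercised against
  simulated nulls and signed synthetic effects, not against an emulated
  evolutionary mechanism.
* Commonality components and hierarchical-partitioning effects are
  descriptive decompositions of $R^2$; with strongly collinear
  predictors most variance lands in joint/common shares, and no causal
  reading is implied.
* The inverse-logistic transfer is undefined at $x \ge K$: reconstruction
  from assemblages larger-leaved than anything in the calibration region
  is refused (`NA`), not extrapolated.
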