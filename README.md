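# leafprod

Community leaf size, climate, and ecosystem primary productivity.

`leafprod` is an R package plus analysis workflow for macroecologists and
palaeoecologists who want to (a) relate gridded community mean leaf size
of woody dicots to climate, (b) build **transfer functions** that predict
ecosystem gross and net primary productivity (GPP, NPP, gC m⁻² yr⁻¹) from
community mean leaf size, and (c) test how far such functions generalise
to an independent region — the statistical basis for reconstructing
palaeo-productivity from fossil leaf assemblages.

## The core model

Community mean leaf size per 50 × 50 km cell is the unweighted mean over
the species present of each species' leaf length, width, or elliptical
area proxy ⅔·L·W. The trait–climate relationship is the logistic

    y = K / (1 + exp(α − r x)),

and, solved for the predictor, the same (K, α, r) triple gives the
inverse-logistic transfer function

    y = (1/r) · (α − ln(K/x − 1)),   0 < x < K,

mapping community mean leaf size x to productivity y. Transfer accuracy is
summarised by SE = √(Σ(y_est − y_real)²/(n−1)) and SE% = 100·SE/range(y).
The package fits the inverse logistic by an exact inner OLS profiled over
K, which recovers noiseless generating parameters to ~10⁻⁹ relative error.

Around that core sit the supporting statistics the inference chain needs:
Dutilleul's modified t-test (spatially corrected significance via an
effective sample size), hierarchical partitioning and three-way
commonality analysis of R², Blomberg's K with a vectorised permutation
test, piecewise structural equation models with exact path-product effect
decomposition, and a fully seeded synthetic-data generator (autocorrelated
climate fields, trait-coupled species niches, Bernoulli ranges,
birth–death phylogenies with tunable signal) so the entire chain is
testable offline.

## Worked example

Simulate a study region, fit the six trait × productivity transfer
functions, and validate the headline model on an independently simulated
sister region:

```r
library(leafprod)

scenario <- leaf_scenario(nx = 20, ny = 20, n_species = 200, seed = 3)
cfg <- pipeline_config(scenario, seed = 3,
                       stages = c("transfer", "cross_region"))
res <- run_pipeline(cfg)

res$transfer$models$GPP_length
#> inverse-logistic transfer (GPP ~ length, n = 305, excluded 0): K = 12.09, alpha = 1.484, r = 0.001903, R2 = 0.9288

res$transfer$table[, c("productivity", "trait", "K", "alpha", "r", "r2", "se_pct")]
#>                productivity      trait      K alpha        r     r2 se_pct
#> GPP_length              GPP     length 12.086 1.484 0.001903 0.9288  5.970
#> GPP_width               GPP      width  7.679 1.462 0.001120 0.9136  6.575
#> GPP_lw_product          GPP lw_product 34.748 2.496 0.002370 0.9256  6.102
#> NPP_length              NPP     length 11.880 1.556 0.003808 0.9316  6.830
#> NPP_width               NPP      width  7.600 1.495 0.002207 0.9137  7.671
#> NPP_lw_product          NPP lw_product 34.957 2.587 0.004618 0.9264  7.087

res$cross_region$evaluation
#> transfer evaluation (n = 294): SE = 73.163, SE% = 6.852, R2 = 0.9157, obs~pred slope = 0.997
```

Reading the output: each row is one transfer function; `K` is the fitted
leaf-size asymptote (cm or cm², predictions exist only for x < K), `r2`
its coefficient of determination against generated productivity carrying
8% range noise, and `se_pct` the standard error of estimate as a
percentage of the observed productivity range. The cross-region block
applies region A's GPP–length model to a region simulated with the same
generating parameters but a different seed: an observed-vs-predicted
slope near 1 with high R² is what "the transfer function generalises"
means operationally.

The numbered scripts under `analysis/` run the same chain as a narrative
workflow — simulation, gridding and community means, trait–climate models
with modified t-tests and hierarchical partitioning, transfer functions
and SEMs, cross-region validation, and phylogenetic signal — writing
their tables under `results/`.

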