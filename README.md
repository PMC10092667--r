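# seabirdDD

Two-stage Bayesian analysis of density dependence in colonial seabird
population dynamics, built for annual colony count programmes (counts of
breeding pairs, or of individuals with a latent conversion to pairs) and the
question of whether environmental variation shapes population regulation.

**Who it is for.** Population ecologists with long colony count time series
who want observation-error-aware estimates of density dependence, and who
want to relate those estimates across colonies to gridded environmental
fields — plus a fully synthetic test world so every stage can be validated
without access to any monitoring data.

## The models

**Stage 1.** For each colony the true abundance `N_t` (pairs) follows a
stochastic Ricker map, in three nested variants:

    M0:  N_t = N_{t-1} · exp(β0 + ε_t)
    M1:  N_t = N_{t-1} · exp(β0 + β1·N_{t-1} + ε_t)
    M2:  N_t = N_{t-1} · exp(β0 + β1·N_{t-1} + β2·N_{t-2} + ε_t)

with `ε_t ~ N(0, σ²)`, observed through `y_t ~ Poisson(N_t)` (pairs) or
`y_t ~ Poisson(K_t·N_t)` (individuals, `K_t ~ N(m_kt, s_kt²)` from a GAM
smooth of empirical ratios). `β1 < 0` is direct negative density dependence.
Priors: `β0 ~ U(log 0.2, log(1 + c/2))` from clutch size `c` and a survival
floor; `β1, β2 ~ U(−10, 10)`; `σ ~ U(0, 2)`; initial state uniform over the
range of the first four counts. Fitting is adaptive Metropolis-within-Gibbs
(compiled, ~0.3 s per series at desk scale), missing counts are latent, and
models are compared by conditional DIC with posterior-predictive Bayesian
p-values as fit checks. Cross-species strength is `exp(0.1·N̄·β1)`, the
multiplicative growth-rate change for a 10% abundance increase.

**Stage 2.** Per species and environmental variable, an errors-in-variables
regression of the stage-1 estimates `D̂_s` (posterior mean of β1, with
posterior SD as known measurement error) on the metric:

    D̂_s ~ N(D_s, sd_s²),   D_s ~ N(α + β·env_s, σ_D²)

Gibbs-sampled with conjugate updates. Evidence for the hypothesized
direction (SST/SSH negative — climate variation strengthens density
dependence; CHL/TF positive — resource variation weakens it) is categorized
`==` (≥95% posterior mass), `=` (≥90%), `!=!=`/`!=` contrary, with
`R² = 1 − σ²_model/σ²_null`. Environmental metrics are the breeding-season
per-pixel temporal SD averaged (climate) or spatially SD-ed (resources) over
each species' foraging buffer, by haversine distance on ~10 km monthly
grids.

## Worked example

```r
library(seabirdDD)

# a synthetic colony with strong density dependence (equilibrium 200 pairs)
sim <- simulate_colony_counts(
  sim_spec("M1", beta0 = 0.5, beta1 = -2.5e-3, sigma_eps = 0.1,
           n_years = 30, N0 = 200, missing_fraction = 0.1, seed = 42))

gull <- species_params("lesser black-backed gull", clutch_max = 3,
                       foraging_range_km = 141)
fit <- fit_state_space(sim$series, model_spec("M1", gull),
                       mcmc_config(seed = 1))
fit
#> <ssm_fit> sim_42, model M1, 4500 draws, converged: TRUE (max Rhat 1.008)
#>            mean       sd      q2.5     q97.5
#> beta0  0.458601 0.226950  0.030274  0.866400
#> beta1 -0.002325 0.001138 -0.004363 -0.000175
#> sigma  0.096819 0.025654  0.050307  0.151587

compute_dic(fit)
#> DIC 247.0 (Dbar 219.6, pD 27.4)
posterior_predictive_pvalue(fit)
#>   discrepancy bayesian_p
#> 1        mean  0.5145556
#> 2          sd  0.4820000
classify_dd_evidence(fit)
#> [1] "negative_dd"
dd_strength(mean(fit$draws$params[, "beta1"]), mean_observed_size(fit))
#> [1] 0.9549
```

Reading: the generating values (β0 = 0.5, β1 = −0.0025, σ = 0.1) sit inside
their 95% credible intervals; both Bayesian p-values are near 0.5 (adequate
fit); ≥95% of the β1 posterior is negative, so the colony is classified as
density dependent; and a 10% rise above the mean population multiplies the
annual growth rate by 0.955.

The full pipeline — filtering, M0/M1 fits, assessment, environmental
metrics, stage-2 regressions — runs from one config:

```r
paths <- make_demo_dataset("demo", seed = 1)        # counts, grids, truth
run_pipeline(list(counts = paths$counts, colonies = paths$colonies,
                  species_config = paths$species,
                  conversion = paths$conversion,
                  grids = list(SST = paths$grid_SST, SSH = paths$grid_SSH,
                               CHL = paths$grid_CHL, TF = paths$grid_TF),
                  outdir = "demo/out", seed = 1))
```

writing `filtering_report.csv`, `assessment.csv` (DIC, ΔDIC, Bayesian p,
classification, strength ± CI), `env_metrics.csv`, `dd_env_regression.csv`
(slope, CI, % posterior in expected direction, category, R²) and a JSON
sidecar with seed and config hash. A command-line front-end with the same
stages as subcommands is in `inst/exec/seabirdDD-cli.R`.

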