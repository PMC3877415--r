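# survbma

Bayesian model-averaged parametric survival analysis for right-censored
data with continuous covariates.

Survival studies routinely face a model-choice dilemma: a single Weibull
regression, a finite mixture of Weibulls (heterogeneous subgroups), and a
cure-rate model (a fraction of subjects never experiences the event) can
all fit the same cohort plausibly, and inferences conditional on one
winner ignore the uncertainty in that choice.  `survbma` fits all three
models by MCMC and combines them by BIC-approximated Bayesian model
averaging (BMA), for biostatisticians analysing cohorts of the
gene-expression-signature kind: a few hundred patients, substantial right
censoring, a handful of standardised continuous covariates, optional
phenotype subgroups for stratified refits.

## Models and statistics

All three models are built on the Weibull law with shape `α` and
log-scale `λ = log γ`:

    f(t) = α t^(α−1) e^λ exp(−t^α e^λ),   S(t) = exp(−t^α e^λ),
    h(t) = α t^(α−1) e^λ

1. **Weibull regression** — covariates act on the log-scale,
   `λ_i = x_i′β`; priors `α ~ Gamma(0.01, 0.01)`, `β_j ~ N(0, 100)`.
2. **Weibull mixture** — `K` components with weights `w ~ Dirichlet(1)`,
   per-component shapes and coefficients (`λ_im = x_i′β_m`), latent
   allocations sampled by Gibbs, and post-hoc label-switching correction
   toward the approximate-MAP pivot (`reorder_chain()`).
3. **Promotion-time cure model** — `N_i ~ Poisson(θ_i)`,
   `θ_i = exp(x_i′β)`, latent Weibull cause times; population survival
   `exp(−θ_i F(t))` and cure fraction `exp(−θ_i)`.  Default sampler
   collapses the latent counts; a data-augmented Gibbs variant is kept as
   a cross-check.

Models are compared through `BIC_s = −2 ℓ̂_s + d_s log(n_events)` (the
BIC's `n` is the **event count**, the standard effective sample size
under censoring) and weighted by

    w_s ∝ exp(−BIC_s / 2) · p(S = s)

(`bma_weights()`), with Bayes factors, model-averaged posterior
predictive simulation (`bma_predictive()`), and per-subject 95%
posterior prediction intervals with coverage summaries
(`predictive_intervals()`, `coverage()`).  A synthetic-data module
generates from each model, including a `dlbcl-like` preset (n = 219,
five standardised covariates, three phenotype levels, ~37% censoring)
so the whole pipeline is testable without any external data.

## Worked example

Simulate a cohort from the cure model (baseline cure fraction 0.35,
published-scale gene effects), fit all three models, and average:

```r
library(survbma)
beta_cure <- c(log(-log(0.35)), -0.3151, -0.2821, 0.189, 0.3303, -0.3039)
data <- simulate_cure_data(n = 219, beta = beta_cure, seed = 42)
data
#> Right-censored survival dataset: 219 subjects, 138 events (63.0%), 6 covariate column(s) incl. intercept

km <- kaplan_meier(data)
km_surv_at(km, c(5, 10, 20))
#> 0.379 0.370 0.370        # the plateau is the footprint of the cured group

fits <- list(
  weibull = fit_weibull(data, config = chain_config(20000, 5000, seed = 43)),
  mixture = fit_mixture(data, K = 2, config = chain_config(20000, 5000, seed = 44)),
  cure    = fit_cure(data,    config = chain_config(20000, 5000, seed = 45)))
sums <- lapply(fits, model_fit_summary)
bma  <- bma_weights(vapply(sums, function(s) s$bic, numeric(1)))
bma
#>     model      bic       weight
#> 1 weibull 657.4865 2.193647e-02
#> 2 mixture 682.2324 9.282695e-08
#> 3    cure 649.8917 9.780634e-01
```

The cure model (the true generator) takes essentially all the weight;
the mixture's 8 extra parameters are not worth their BIC penalty.  Its
posterior:

```r
summarize_chain(fits$cure$chain)
#>   parameter   mean     sd   lower   upper
#> 1     alpha  0.927 0.1202  0.6782  1.1398
#> 2    lambda -1.326 0.7030 -3.3845 -0.6904
#> 3     beta0  0.432 0.6130 -0.0974  2.2723
#> 4     beta1 -0.255 0.0904 -0.4260 -0.0716
#> ...
mean(population_cure_summary(fits$cure))
#> 0.276                      # posterior mean fraction of cured subjects

set.seed(46)
iv <- predictive_intervals(fits, data, n_draws_out = 1000, weights = bma$weights)
coverage(iv, data)
#> 97.7                       # % of observed times inside their own 95% interval
```

`beta1`, `beta2` and `beta5` are credibly negative: higher scores on
those signatures mean more latent causes (higher `θ`), hence a lower
cure probability and shorter survival.  The model-averaged prediction
intervals cover 97.7% of the observed times — close to, and slightly
above, the nominal 95%, as expected when a high-weight correct model
dominates the average.

## Command line

The same pipeline runs from the shell via `exec/survbma`
(or `survbma_cli()` from R):

```sh
Rscript exec/survbma simulate --preset dlbcl-like --model cure --seed 7 --out run/
Rscript exec/survbma fit      --data run/dataset.csv --out run/ --seed 7
Rscript exec/survbma average  --fits run/
Rscript exec/survbma predict  --data run/dataset.csv --fits run/ --seed 7
Rscript exec/survbma report   --fits run/
```

`simulate` writes the dataset CSV plus a JSON sidecar holding the true
parameters and latent labels (kept out of the dataset so fits cannot
leak them); `fit` writes chain CSVs and summary JSONs (posterior means,
95% CIs, maximised log-likelihood, `d_s`, event count, BIC), with
`--stratify` for per-phenotype refits; `average`/`predict`/`report`
produce the weight table, coverage table and a plain-text report.

## Documentation

The methods vignette (`vignettes/model-averaged-survival.Rmd`) describes
the three models and their priors, the BIC/BMA machinery, the
label-switching correction, what the synthetic-data generator does and
does not emulate, numerical choices, and known limitations.
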