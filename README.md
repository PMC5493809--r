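# bden — Bayesian dynamic elastic net for hidden influences in ODE models

Mechanistic ODE models of molecular networks are usually incomplete or
partially wrong: unmodelled inputs, missing reactions and spurious reactions
all show up as systematic discrepancies between model predictions and
time-series data. `bden` estimates, for every state variable of a given
*nominal* model

```
dx/dt = f(x, u, t) + w(t),        y_l = h(x(t_l)) + eps_l,
```

the additive hidden influence `w_i(t)` that the data demand, under a
hierarchical Bayesian elastic-net prior that makes the influences **sparse
across nodes** (only a few equations are wrong) and **smooth across time**.
The measurement-noise variance is marginalized under an inverse-gamma prior,
giving a Student-t likelihood per residual. Sampling is by a sequential
Metropolis-within-Gibbs algorithm over the influence values at each
measurement time, with Gibbs refreshes of the elastic-net hyper-parameters.

The posterior answers two questions:

1. **Where is the model wrong?** Nodes are ranked by the influence score
   `∫ |posterior mean w_i(t)| dt` (trapezoidal rule).
2. **Why?** Lagged cross-correlations between influences (`Corr HI`) and
   between influences and estimated states (`Corr State`) classify each
   flagged node: `(−,+)` missing stimulation, `(+,−)` missing inhibition,
   `(−,−)` wrong stimulation, `(+,+)` wrong inhibition, anything weak →
   exogenous input.

The package ships ODE fixtures from the systems-biology literature
(JAK-STAT signalling, yeast G protein cycle, EpoR processing, alpha-pinene
isomerization, plus synthetic UV-B and DREAM6-style networks and five
canonical network motifs), a seeded synthetic-data generator, and a
benchmark harness scoring localization and interaction detection by ROC AUC
and Brier score. Audience: modellers who already have a mechanistic ODE
model and data that it does not quite fit.

## Worked example

Remove the nucleocytoplasmic shuttling from the JAK-STAT model, simulate
data from the true system at 2.5% noise, and let the method find the error:

```r
library(bden)
m    <- build_model("jak-stat")                 # true system (4 species)
nom  <- variant_model(m, "no-nuclear-export")   # nominal model with the error
d    <- simulate_dataset(m, noise_level = 0.025, seed = 11)
fit  <- bden(nom, d, bden_control(n_samples = 1500, n_burnin = 600,
                                  thin = 3, seed = 1, n_chains = 2))
round(summary(fit)$influence_score, 3)
#>  STAT5 STAT5p STAT5d STAT5n
#>  0.202  0.009  0.020  0.144
diagnose(fit)
#> Hidden-influence diagnosis for model 'jak-stat:no-nuclear-export'
#> Influence scores (ranked):
#>   STAT5  STAT5n  STAT5d  STAT5p
#> 0.20200 0.14400 0.01980 0.00918
#> Flagged nodes and classification:
#>    node partner               label    corr_hi corr_state
#>   STAT5  STAT5n missing-stimulation -0.8182161  0.9676203
#>  STAT5n   STAT5 missing-stimulation -0.8182161  0.8944536
```

The two nodes of the removed reaction dominate the influence ranking, their
influences are strongly anticorrelated, and the influence at STAT5 is
positively correlated with the nuclear-STAT5 state — the
missing-stimulation signature pointing from STAT5n to STAT5, i.e. exactly
the removed back-translocation. `plot(fit)` shows the data against the
posterior predictions and the hidden influences with credible bands.

A thin command-line wrapper is installed under
`system.file("scripts", "bden", package = "bden")` with subcommands
`models`, `simulate`, `fit`, `diagnose` and `benchmark`.

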