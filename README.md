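# kinlabel

Estimation of lymphocyte turnover rates from stable-isotope (deuterium)
labeling experiments, under explicit kinetic heterogeneity.

## The problem

Labeling DNA with deuterium (heavy water or deuterated glucose) is the
standard way to measure how fast human lymphocyte populations turn over in
vivo: the fraction of labeled DNA L(t) rises while label is administered
(for T days) and falls after withdrawal. Interpreting these curves is
model-dependent, and historically three different-looking models — an
asymptote model, a "source" model and a two-rate heterogeneity model —
have been fitted to them. Those three are mathematically identical: they
predict the same curve, with one exponential rate and one maximum labeling
level, and they identify only the population's **average turnover rate**.

`kinlabel` implements that classical curve together with models of
*explicit kinetic heterogeneity*, in which the population is a continuum
of subpopulations with turnover rates p drawn from a distribution f(p):

    L(t) = ∫ L₁(t; p) f(p) dp,     L₁(t; p) = e^(−p·max(t−T,0)) − e^(−p·t)

For gamma-distributed rates (mean p̄, shape k) the integral has the closed
form L(t) = 1 − (1 + p̄·t/k)^(−k) during labeling, with exponential
(k = 1), homogeneous (k → ∞), truncated-gamma and finite-mixture variants.
These models reproduce experimental regularities the classical model
cannot: non-exponential uplabeling and delabeling, and a per-capita
initial delabeling rate p* = p̄ + σ²/p̄ after short labeling that relaxes
to p̄ after long labeling — a factor of exactly 2 when rates are
exponentially distributed.

The package is aimed at quantitative immunologists analyzing labeling
time courses: it provides the model curves, derived kinetic quantities
(average turnover, initial delabeling rate, contribution profiles, tail
plausibility screens), variance-stabilized nonlinear least-squares fitting
with parameter sharing across subjects, residual-bootstrap confidence
intervals, partial F-tests and AIC for model selection, an independent
quadrature/Monte-Carlo oracle validating every closed form, and a
synthetic-data engine for parameter-recovery studies.

## Worked example

Simulate a 7-day labeling experiment on a population with
gamma-distributed turnover rates (average 0.01/day, shape 0.5), fit the
gamma model, and bootstrap confidence intervals:

```r
library(kinlabel)

cfg <- synthetic_config(gamma_params(pbar = 0.01, k = 0.5),
                        T_label = 7, seed = 42)
ds  <- generate_dataset(cfg)
fit <- fit_model(ds, "gamma", n_starts = 10)
fit <- bootstrap_ci(fit, n_boot = 200, seed = 1)
print(fit)
#> <labeling_fit> model: gamma
#>   subjects: sim1
#>   rss (transformed scale): 0.000501243  n_obs: 11  free parameters: 2
#>   sim1: pbar=0.010289, k=0.62735, alpha=1, tau=0  avg turnover=0.010289/day
#>   bootstrap (200 resamples, seed 1):
#>            quantity estimate    lower   upper
#> 1              pbar  0.01029 0.009799 0.01087
#> 2                 k  0.62735 0.484860 0.87433
#> 3 avg_turnover|sim1  0.01029 0.009799 0.01087
```

The fitted average turnover rate is 0.0103/day with a 95% bootstrap
interval [0.0098, 0.0109] that covers the generating value 0.01/day, and
the fitted shape 0.63 passes the biological-plausibility screen (k > 0.1;
smaller shapes would attribute much of the turnover to implausibly fast
subpopulations — see `fraction_above()`). The headline heterogeneity
effect is available analytically:

```r
d <- dist_exponential(0.01)
initial_delabeling_rate(d, 1e-8) / initial_delabeling_rate(d, 1e12)
#> [1] 2
```

Real datasets enter as CSV files with columns
`subject,time_days,frac_labeled,T_days` (`read_datasets()`, `--percent`
for percent-scale data); a synthetic example ships in
`inst/extdata/synthetic_labeling_example.csv`. A command-line interface
wraps the same machinery:

```sh
Rscript inst/scripts/kinlabel.R simulate --model gamma --par pbar=0.01,k=0.5 \
    --T 7 --seed 1 --out sim.csv
Rscript inst/scripts/kinlabel.R fit --data sim.csv --model gamma --boot 1000 \
    --seed 1 --out-dir results/
Rscript inst/scripts/kinlabel.R compare --data sim.csv --models asymptote,gamma
```

See `vignettes/kinetic-heterogeneity.Rmd` for the models, their
assumptions, numerical choices, and what the synthetic experiments do and
do not validate.

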