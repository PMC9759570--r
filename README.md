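# steatoPK

Pharmacokinetic and statistical analysis of drug-cocktail elimination in a
mouse model of diet-induced periportal hepatic steatosis.

Mice fed a high-fat diet with low methionine/choline content for two or four
weeks develop periportal steatosis of increasing severity. Because the
drug-metabolizing CYP enzymes sit pericentrally, the interesting question is
whether periportal fat accumulation nevertheless changes drug elimination.
The experimental readouts are (i) blood concentration time courses of a
probe-drug cocktail (caffeine for CYP1A2, midazolam for CYP3A4, codeine for
CYP2D6) sampled at ten scheduled times over six hours, and (ii) per-animal
steatosis features: surface percentages from tile-classified histology,
hepatic triglycerides, and ex-vivo CYP activities.

`steatoPK` implements the full analysis chain over these readouts, driven by
a calibrated synthetic-data generator so every stage runs without any
external download.

## The model

Each replicate's concentration time course is described by the single-peak
elimination curve

    x(t) = t * exp(B - A*t)

with rate parameter `A` (1/h) and log-amplitude `B`. The curve rises to its
maximum at `t_peak = 1/A` with `x_peak = exp(B-1)/A`, then decays
exponentially. Derived quantities are the half-life `t_1/2` (time from the
peak to half the peak, solved by a bracketed root-finder; `A * t_1/2` is a
universal constant ≈ 1.6784) and the decay-phase AUC, the integral of the
fitted curve from `t_peak` to 6 h (closed-form antiderivative).

Estimation comes in two flavours:

* **Per-replicate least squares** (`fit_replicate`, `derive_pk`):
  Levenberg–Marquardt on the linear concentration scale with box
  constraints and a seeded five-point multistart.
* **Pooled Bayesian inference per condition** (`sample_posterior`): the
  likelihood `L(A,B,σ) = ∏_j ∏_k N(m_j(t_k); x(t_k), σ²)` pools replicates
  under one curve and one noise σ, with uniform priors A, B ∈ [0, 100] and
  σ ∈ [0, 1000]. Sampling uses an adaptive parallel-tempering
  random-walk sampler (4 chains, geometric temperature ladder), Geweke
  burn-in with a minimum cut of 100, initial-positive-sequence effective
  sample sizes, and 95% posterior-predictive credibility bands whose
  non-overlap at a time point is read as a significant difference between
  conditions.

Group statistics follow the study's conventions: ordinary one-way ANOVA and
Tukey HSD for group differences; Pearson correlation with Fisher-z 95% CI,
two-tailed p, and magnitude-based strength labels (≥ 0.7 strong, 0.5–0.7
moderate, 0.3–0.5 fair, < 0.3 negligible); correlation matrices with
Benjamini–Hochberg-adjusted stars. Steatosis quantification aggregates
classified tiles (micro/macro/non-steatotic, lumen excluded) into surface
percentages, grades severity by the clinical 33/66% rule, and forms
micro:macro ratios rounded half-up to one decimal.

## Worked example

```r
library(steatoPK)

fx <- fixture_worked_example()          # packaged worked example, A = 2.168, B = 5.397
fit <- fit_replicate(fx$series)
fit
#> Least-squares fit: A = 2.1680, B = 5.3970 (SSE = 0, 9 points)

derive_pk(fx$series)
#> Derived PK quantities (A = 2.168, B = 5.397):
#>   t_peak = 0.4613 h, x_peak = 37.46 ng/ml
#>   t_1/2  = 0.7741 h, AUC(decay) = 34.55 ng*h/ml
```

The fitted rate `A = 2.168` puts the peak at 0.46 h (within the 15–60 min
window expected for the cocktail), the concentration halves 0.77 h after
the peak, and the decay-phase exposure is 34.55 ng·h/ml.

Pooled Bayesian estimation on synthetic codeine replicates:

```r
cfg <- default_config()
tcs <- generate_timecourses(cfg, seed = 3)
reps <- Filter(function(s) s$group == "control" && s$analyte == "codeine", tcs)
sample_posterior(reps, n_samples = 20000, seed = 11)
#> Posterior ensemble: 19900 retained draws (20000 requested, burn-in 100)
#>   posterior means: A = 2.161, B = 5.407, sigma = 3.187
#>   ESS: A = 655, B = 652, sigma = 2814
```

The posterior concentrates around the generating truth (A = 2.168,
B = 5.397) with a posterior σ near the configured measurement noise.

## Analysis workflow

The `analysis/` directory holds the numbered pipeline drivers, each a thin
narrative script over the package functions, writing its tables under
`results/`:

1. `01_simulate.R` — cohort simulation (features + time courses)
2. `02_fit_pk.R` — per-replicate fits, PK table, group AUC ANOVA/Tukey
3. `03_bayes_uq.R` — pooled posteriors, credibility bands, overlap calls
4. `04_steatosis.R` — tile aggregation, severity grades, micro:macro ratios
5. `05_correlations.R` — feature × PK correlation matrix with BH stars

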