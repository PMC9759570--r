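---
title: "Methods: elimination-curve pharmacokinetics and pooled Bayesian uncertainty in the steatosis model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elimination-curve pharmacokinetics and pooled Bayesian uncertainty in the steatosis model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatoPK)
```

## The elimination curve and its derived quantities

After a bolus injection of the probe-drug cocktail, each analyte's blood
concentration rises to a single maximum and then decays exponentially. The
package models this with

$$x(t) = t \, e^{B - A t},$$

the solution of $\dot{x} = (1 - A t)\, e^{B - A t}$ with $x(0) = 0$. The
two parameters have clean roles: $A$ (1/h) sets the decay rate and pins the
peak at $t_{peak} = 1/A$; $e^B$ is an amplitude. This is deliberately not a
mechanistic absorption model — it is the simplest smooth curve with the
observed rise-then-decay shape, and every derived quantity has a closed or
near-closed form:

* $t_{peak} = 1/A$ (exact; `peak_time_numeric()` retains the numerical
  maximization route as a cross-check),
* $x_{peak} = e^{B-1}/A$,
* $t_{1/2}$: the root of $x(t) = x_{peak}/2$ beyond the peak, minus
  $t_{peak}$. Substituting $u = A t$ shows $A\,t_{1/2}$ is a universal
  constant ($\approx 1.6784$), independent of both parameters — a useful
  invariant that the tests assert across random parameter draws.
* decay-phase AUC: $\int_{t_{peak}}^{6} x(t)\,dt$ by the closed-form
  antiderivative $-e^B (t/A + 1/A^2) e^{-A t}$. Quadrature is used only as
  a test oracle; the runtime path is exact and fast.

Units are fixed throughout: hours and ng/ml, matching the sampling schedule
(pre-dose, 15 min, 30 min, 1 h, 1.5 h, 2 h, 2.5 h, 3 h, 4 h, 6 h) and the
UPLC-MS/MS reporting scale.

### Half-life root bracketing

The root is searched on $[t_{peak},\, t_{peak} + 60/A]$ with Brent's method
at $10^{-10}$ h absolute tolerance. The upper end is far beyond any
plausible half-life (at $u = A t = 61$ the curve has fallen by $\sim e^{-60}$
relative to the peak), so for valid parameters the bracket always holds;
the explicit error guards numeric misuse rather than a reachable state.

## Per-replicate least squares

`fit_replicate()` estimates $(A, B)$ for each animal × analyte series
independently, minimizing the residual sum of squares on the **linear**
concentration scale with Levenberg–Marquardt under box constraints
$[10^{-6}, 100]^2$. The linear scale is not a convenience: the Bayesian
likelihood assumes additive Gaussian noise on $x(t)$, and linear least
squares is the $\sigma$-profiled maximum-likelihood estimate of that same
model, so the two estimation paths target the same optimum. The box matches
the Bayesian prior for the same reason.

Starting values come from a heuristic (the decay limb satisfies
$\ln(c/t) = B - A t$, so the tail slope of $\ln(c/t)$ gives $A_0$, clamped
to $[0.05, 50]$, and $B_0$ is solved from the observed maximum), plus four
seeded perturbations; the lowest-SSE start wins. The objective is benign in
practice — the multistart is cheap insurance against heavy-noise
bimodality, and makes the result a deterministic function of (series,
seed).

Two data-handling choices the study text leaves open are fixed here and
tested: the pre-dose $t = 0$ sample is retained but carries no information
(the model forces $x(0) = 0$), and post-dose values flagged below the limit
of quantification are dropped from the fit, since a censored value carries
no calibrated magnitude. An alternative (treating sub-LOQ values as LOQ/2)
was not pursued; with ten points per series and at most a couple of
censored tail points, the fitted decay is dominated by the quantifiable
mid-curve samples.

## Pooled Bayesian uncertainty quantification

Per dietary condition, all replicates of one analyte are pooled under one
curve and one noise level:

$$L(A, B, \sigma) = \prod_{j=1}^{N} \prod_{k=1}^{T}
\frac{1}{\sqrt{2\pi}\,\sigma}
\exp\!\left(-\frac{(x(t_k) - m_{j}(t_k))^2}{2\sigma^2}\right),$$

with uniform priors $A, B \sim U[0, 100]$ and $\sigma \sim U[0, 1000]$
ng/ml. The single shared $\sigma$ follows from the likelihood's form; a
per-replicate curve would be the least-squares path instead. Pooling is a
modelling decision: the posterior describes the condition's typical
dynamics, not any individual animal, and between-animal variability ends up
absorbed into $\sigma$.

### Sampler design

`sample_posterior()` runs an adaptive parallel-tempering random-walk
Metropolis sampler, written for this likelihood (the per-iteration cost is
$O(T)$ via per-time sufficient statistics; the core loop is compiled):

* **Ladder**: geometric inverse temperatures from 1 down to 0.1 across 4
  rungs — the conventional PT setup when only "four chains" is specified.
  Adjacent-rung state swaps are proposed every 100 iterations.
* **Proposals**: component-wise Gaussian random walks. Scales adapt by
  Robbins–Monro towards the 0.234 acceptance target during the first
  quarter of the run only, so detailed balance holds exactly afterwards.
* **Budget**: the default is 20,000 samples. The study-scale budget of
  200,000 is one argument away (`n_samples = 200000`); the package default
  is the desk-scale setting used by the test-suite and the analysis
  drivers, chosen so a full pooled fit takes well under a second while
  still leaving post-burn-in effective sample sizes in the hundreds.
* **Initialization**: data-informed (a least-squares fit of the first
  replicate, jittered per chain) — with flat priors there is nothing to be
  gained from dispersed random starts on this 3-parameter posterior, and
  the Geweke cut removes any initialization transient.

### Convergence handling

Burn-in is set by the Geweke stationarity test: scanning candidate cut
points from the floor of 100 upward, the first cut is taken at which the
z-score comparing the leading 10% against the trailing 50% of the remaining
chain satisfies $|z| < 2$ for every parameter. At least 100 samples are
always discarded even when the diagnostic would allow fewer. Window
variances use the AR-fit spectral density at frequency zero; one numerical
guard is added on top of the textbook recipe: when a window's estimated
autocorrelation time rivals a tenth of its own length — the signature of a
level shift sitting inside the window, which inflates the variance estimate
and can mask arbitrarily large mean differences — the window is treated as
failing the diagnostic outright. Without the guard, a shift placed right at
the candidate cut can slip under the z-threshold.

Effective sample sizes use $N / (1 + 2\sum_t \rho_t)$ with the
initial-positive-sequence truncation (summation stops before the first
non-positive sum of adjacent autocorrelation pairs), capped at $N$. The
study reports ESS above 13,900 for its 200,000-sample chains; at the
desk-scale default the corresponding figure is proportionally smaller and
is reported per parameter in the ensemble object rather than asserted
against a threshold.

### Credibility bands

`posterior_predictive_band()` pushes every retained draw through the curve
over a time grid and summarizes pointwise: equal-tailed percentile
intervals (2.5/97.5 at the default level — "95% credibility interval" is
read as equal-tailed, no HPD machinery) with the pointwise mean as the
center line. The default band describes the **model output**, i.e. the
noise-free curve; `include_noise = TRUE` adds a per-draw measurement-noise
sample for a predictive band on new observations. Non-overlap of two
conditions' bands at a time point is the significance reading;
`bands_overlap_at()` uses closed intervals, so touching bands count as
overlapping — the conservative call.

## Group statistics

The statistics layer deliberately routes through the standard R machinery —
`aov`/`TukeyHSD`, `cor.test`, `p.adjust(method = "BH")` — behind thin,
validating wrappers, with the test-suite holding independent hand oracles
(the ANOVA decomposition, the Fisher-z interval, the BH step-up rule, a
Monte-Carlo studentized-range distribution) against them. Choices worth
recording:

* Ordinary (equal-variance) ANOVA, no Welch correction.
* Fisher-z construction for the correlation CI — the standard choice at
  these group sizes; the construction is not otherwise specified.
* Strength boundaries closed at the lower edge: $|r| = 0.5$ is moderate,
  $|r| = 0.3$ is fair, anchored by the "≥ 0.7 is strong" end of the
  convention.
* The correlation matrix adjusts **all** off-diagonal p-values jointly with
  BH (not per feature family); stars at 0.05/0.01/0.001.

## Steatosis quantification

Tile classification itself (the machine-learning part) is out of scope;
the package starts from classified tiles. `aggregate_tiles()` computes
surface percentages over non-lumen tiles, requiring at least 30 tiles per
image. Severity grading takes the 33–66% band as closed on both ends
(33 is moderate, 66 is moderate) — the prose convention is ambiguous at
the exact boundaries, so the choice is fixed and tested. The micro:macro
ratio rounds half-up to one decimal, matching the "x.y:1" printing
convention; note that ratios computed from already-rounded group means can
differ in the last decimal from ratios computed on unrounded data (the
two-week group's 48.6/20.7 gives 2.3, while the unrounded study data print
2.4:1) — the package always computes from its actual inputs. Lobe averaging
weights by lobe area by default ("mean severity based on the total surface
covered by the individual lobes" admits either reading; the unweighted mean
is available via `weighted = FALSE`).

## The synthetic-data generator

`default_config()` fixes the study conditions: three groups (control,
2-week, 4-week HF-diet), 6 animals per group, the ten scheduled sampling
times, and per-group feature means ± SDs exactly as printed — lipid
droplets 9.3 ± 1.3% (2 wk) and 13.9 ± 2.7% (4 wk); microvesicular surface
48.6 ± 12.9% vs 33.4 ± 10.2%; macrovesicular 20.7 ± 7.1% vs 39.9 ± 8.6%;
triglycerides 99.6 ± 42.3, 252.8 ± 43.0 and 296.1 ± 91.6 nmol/100 mg.
Where the study prints no number the defaults are fixed once at plausible
values: control steatosis surfaces at 1 ± 0.5% (small but nonzero, so no
correlation-matrix column degenerates), CYP activities at magnitudes
consistent with the reported directions (CYP3A and CYP1A lower under the
diet, CYP2E1 roughly doubled at four weeks), elimination truth $(A, B)$
per analyte with peaks inside the observed 15–60 min window, and
measurement noise set to a 10% coefficient of variation at the control
peak.

### Moment-matched truncated normals

Bounded features (percentages in $[0, 100]$, positive concentrations) are
drawn from truncated normals. Naively truncating a normal with the target
mean and SD shifts the realized mean whenever a bound sits within a few
SDs — for control triglycerides (99.6 ± 42.3, truncated at zero) the shift
is about +1.1 nmol/100 mg, which a large-cohort calibration check would
resolve. The generator therefore solves for the **parent** $(\mu, \sigma)$
whose truncated distribution has exactly the configured mean and SD
(closed-form truncated-normal moments inside a two-parameter
Nelder–Mead), so configured moments are the realized moments by
construction, not approximation. Far from the bounds the parent parameters
coincide with the targets. Cross-feature dependence, when requested, enters
through a Gaussian copula so the matched marginals are preserved exactly.

### What the generator does and does not emulate

It reproduces the group structure of the printed summaries, the sampling
design, additive Gaussian measurement noise with zero-clamping and LOQ
flagging, and multinomial tile labels. It does **not** emulate: absorption
mechanics or metabolite stoichiometry (metabolites would simply be further
analytes with their own $(A, B)$), between-animal PK variability within a
group (all animals of a group share the generating curve; the observed
spread is measurement noise), spatial correlation between neighbouring
tiles, or heavier-tailed biological outliers. Passing tests on this
synthetic cohort therefore demonstrate that the estimation and statistics
machinery is correct under the study's own noise model — not that the
model is adequate for any particular real dataset.

## Problem sizes used by the checks

The test-suite and acceptance script run at desk scale, chosen as the
package's own working sizes: generator calibration at $10^5$ animals per
group (Monte-Carlo SE small enough to resolve a 0.1% miscalibration),
credible-interval coverage over 100 seeded runs of 20,000 samples each,
estimator-bias checks at 200 seeded replicates with common random numbers
across noise levels, and the null false-discovery simulation at 500
repetitions of a 20 × 6 feature table. The study-scale sampler budget
(200,000 samples, ESS in the tens of thousands) remains available through
`n_samples`.

## Known limitations

* The elimination curve is empirical; it cannot represent multi-phase
  decay, enterohepatic recirculation, or a delayed absorption peak beyond
  $1/A$.
* The pooled posterior treats replicates as exchangeable noise around one
  curve; a hierarchical (per-animal random effects) model would separate
  biological from measurement variability but is out of scope.
* Uniform box priors make the posterior proper but carry no
  pharmacological information; with very sparse or very noisy data the
  posterior can lean on the box edges.
* The Geweke scan inspects a fixed grid of candidate cuts (21 points up to
  half the chain); pathological chains whose only valid cut lies between
  grid points are cut at the next candidate.
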