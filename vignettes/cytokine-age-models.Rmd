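---
title: "Censored age models for paediatric cytokine reference ranges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored age models for paediatric cytokine reference ranges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoage)
```

## The problem

Whole-blood cytokine release in children changes markedly with age, so a
single "normal range" misclassifies the young. Quantifying that
age-dependence from multiplex bead immunoassay data faces two structural
difficulties. First, concentrations are approximately lognormal with very
large between-subject spread (coefficients of variation of hundreds of
percent are common). Second, the assay only quantifies within its
calibration range: values below the lower limit of quantification (LLOQ)
are left-censored — we know only that they are below the bound — while
values above the upper limit (ULOQ) are extrapolated from the calibration
curve and can be treated as (noisier) measurements. Discarding or
substituting censored values biases every downstream estimate; the
likelihood has to carry the censoring explicitly.

`cytoage` packages the resulting analysis chain: censored univariate
regression for covariate screening, censored nonlinear mixed-effects
models for the age-concentration relationship, percentile (reference
range) curves derived from the fitted distribution, and simulation-based
model diagnostics. Because the underlying clinical dataset is not public,
the package also contains a first-class synthetic-cohort generator that
reproduces the statistical structure the analysis assumes; every method is
tested against data from that generator.

## Model and assumptions

For subject $i$ with age $a_i$ (years), one cytokine under one stimulation
condition is modelled as

$$y_i = m(a_i)\, e^{\eta_i}\, e^{\varepsilon_i}, \qquad
\eta_i \sim N(0, \omega^2), \quad \varepsilon_i \sim N(0, \sigma^2),$$

with $m(\cdot)$ a structural median function. Assumptions: multiplicative
(lognormal) between-subject and residual variability, both age-constant;
random effects independent across subjects; and, in the default
per-condition analysis, independent across conditions. Four median shapes
are provided, all anchored so that $m(0) = \beta_0$ (the expected value in
infancy, pg/mL):

* **M1 linear** $m(a) = \beta_0 (1 + \beta_1 a)$ — valid only while
  positive on $[0, 13]$; the fitter enforces this through its internal
  parameterisation $\beta_1 = (e^{t} - 1)/13$.
* **M2 exponential** $m(a) = \beta_0 e^{\beta_1 a}$ — the reference model;
  a constant percent change per year.
* **M3 exponential-to-asymptote**
  $m(a) = \beta_{asym} + (\beta_0 - \beta_{asym}) e^{-\beta_1 a}$ — a
  physiologic plateau with increasing age.
* **M4 logistic** — a sigmoid transition between $\beta_0$ and
  $\beta_{asym}$ with steepness $\beta_1$ and inflection age $t_{50}$,
  rescaled so the curve starts exactly at $\beta_0$; without rescaling,
  $m(0)$ would depend on $t_{50}$, breaking the "infancy value" reading of
  $\beta_0$.

The exact functional families are a design choice of this package (linear,
exponential and saturating shapes are the natural candidates for growth-
like age trends); the exponential is the default because a constant
relative change per year is both the most parsimonious description of
multiplicative data and the shape the selection procedure most often
prefers on data generated under it. `M0` ($m \equiv \beta_0$) is included
as the age-free null for variance-explained comparisons.

### Censoring

Below-LLOQ observations contribute
$\Phi\!\big((\ln L_{\text{eff}} - \ln m(a) - \eta)/\sigma\big)$ to the
conditional likelihood — the standard cumulative-probability ("M3")
treatment of below-LOQ data in pharmacometrics. The *effective* limit
$L_{\text{eff}}$ is the calibration limit times the condition's dilution
factor (3.2 pg/mL undiluted; 32 pg/mL for the 1:10-diluted SEB and PHA
conditions). Censored rows are stored *at the bound* with a status flag:
the bound is likelihood information, never a measurement. Above-ULOQ
values enter as observed, matching the extrapolation convention; their
extra analytical noise is absorbed by $\sigma$.

### Estimation

The marginal likelihood integrates $\eta$ per subject:
$\ell_i = \ln \int \prod_j \ell(y_{ij}\mid\eta)\,\phi(\eta; 0,
\omega^2)\,d\eta$. Two routes are used:

* subjects with a **single observation**: the integral is available in
  closed form (the log value is marginally normal with variance
  $\omega^2 + \sigma^2$, censored or not), which is both exact and fast;
* subjects with **multiple observations** (pooled/shared-$\eta$ designs):
  adaptive Gauss–Hermite quadrature, default 21 nodes, centred at the mode
  of the integrand and scaled by its curvature. On the package's standard
  fixtures the adaptive rule agrees with 2001-point trapezoid integration
  to better than $10^{-6}$ relative, and raising the order to 41 changes
  the optimum log-likelihood by less than $10^{-4}$ (both are tested).

Optimisation is Nelder–Mead over an unconstrained parameterisation
(log-positive parameters; the M1 slope mapped as above), multi-started
(default 5; the pipeline uses 3) from a log-linear regression fit on the
uncensored rows with seeded Gaussian perturbations, best likelihood kept —
deterministic given data, starts and seed. Standard errors come from a
finite-difference Hessian of the marginal log-likelihood at the optimum on
the natural scale and are flagged unavailable when the Hessian is not
positive definite (common for the boundary-adjacent asymptote model);
estimates remain usable without them.

### Identifiability of $\omega$ and $\sigma$

With one observation per subject — the default unit of analysis, one
cytokine × condition — the marginal law of $\ln y$ is
$N(\ln m(a), \omega^2 + \sigma^2)$: only the *total* log-variance is
identified, and no estimator can split it. The package therefore fixes
$\sigma$ by default at 0.2 (log-SD, ≈ 20% CV, of the order of the assay's
reported intra/inter-assay precision and of residual variability typically
found in such analyses) and estimates $\omega$; `sigma = "estimate"` is
available and appropriate whenever subjects contribute replicates, e.g.
under the shared-$\eta$ pooled mode below. Reported between-subject
variability uses the exact lognormal CV $100\sqrt{e^{\omega^2} - 1}$ —
the familiar $100\,\omega$ approximation is off by >3% already at
$\omega = 0.25$ and useless at the CVs this data regime produces.

### Model selection

Converged fits are ranked by AIC; models within 2 AIC units of the best
are treated as statistically equivalent and the tie resolves toward fewer
parameters, then lower AIC. The VPC (below) is the complementary
simulation-based diagnostic for the short-listed models. A caveat the
package's own simulations make explicit: with n ≈ 271, a cohort age
distribution concentrated between 3 and 8 years, and total log-SD ≈ 0.6,
the linear and exponential shapes are frequently statistically
indistinguishable (their AIC difference is within ±2 in a substantial
fraction of replicate cohorts, and the linear model wins by more than 2 in
some) — the derived quantities (infancy value, 12-year change, IIV CV)
are nevertheless recovered stably across replicates, because the shapes
agree closely over the observed age range. Shape identification, not
parameter recovery, is the fragile part at this design size.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` draws ages from a lognormal calibrated — *after*
truncation to [0.1, 12.8] years — to quartiles 3.5 / 5.3 / 7.9 years
(meanlog 1.80524, sdlog 0.70168, found by matching the truncated quartiles
numerically; the same procedure gives the vitamin-D marginal, median 54
IQR 40–69 truncated to 11–142 nmol/L). Sex is Bernoulli(0.74 boys);
weight-for-age z-scores are Normal(0.25, 1.11), consistent with a median
0.3 and IQR (−0.5, 1.0). Age and vitamin D are coupled by a Gaussian
copula with $\rho = \sin(\pi\tau/2)$ targeting Kendall $\tau = -0.13$
(supplementation is concentrated in infancy); rank correlation is
preserved exactly under the monotone marginal transforms, and a property
test checks recovery within ±0.03 at n = 10⁴. Lifestyle columns (smoke
exposure, diet, pets) are generated inert — no outcome link — mirroring a
screening step that found nothing.

`simulate_concentrations()` applies the model above per panel entry. The
default panel parameterises all 32 cytokine × condition combinations with
an exponential model (infancy value, 12-year value, IIV CV per entry;
$\sigma = 0.2$ throughout). The four unstimulated interleukins that sit
almost entirely below the LLOQ carry no quantifiable age model; they are
simulated flat at a sub-LLOQ median of 2 pg/mL with a representative
200% CV so that heavily censored strata exist in every synthetic dataset.
The subject effect $\eta$ is drawn independently per entry by default
(matching per-condition variability estimates); `eta_mode = "shared"`
scales one deviate per subject × cytokine by each condition's $\omega$,
inducing within-subject correlation across conditions — the two modes
bracket plausible pooled-analysis structures, and neither is claimed to
be the true dependence.

What passing tests on this generator do **not** show about real data: the
generator's variability is exactly lognormal and age-constant, its
censoring occurs exactly at the nominal limits, ages carry no measurement
error, and every cytokine follows its generating family. Real assay data
violate all of these to some degree (skewness beyond lognormal, drift,
batch effects); results here validate the estimators under their own
assumptions, not those assumptions themselves.

## Covariate screening

`screen_covariates()` runs univariate censored Gaussian regressions of log
concentration on each covariate (delegated to `survival::survreg`,
left-censored response), strictly one covariate at a time, two-sided Wald
p-values, significance at 0.05 with *no* multiplicity correction — the
screening is deliberately permissive, and its type-I error is verified by
permutation in the test suite. Cells with more than 50% of observations
below the LLOQ are skipped outright (a skip marker, not a zero): with a
majority of the distribution unobserved, a univariate Tobit slope is
dominated by the censoring model rather than the data. Reporting units are
per year of age, per SD of weight-for-age z-score, girls vs boys, and per
10 nmol/L of vitamin D; effects are shown as percent change per unit,
$100(e^{\alpha_1} - 1)$. Summary tables place censored rows at the bound
and print any quantile at or below the effective LLOQ as a token
(`<3.2`), never as a number; quantiles are type-7 (a display convention —
it affects no estimate).

## Percentile curves and VPC

Reference curves default to the *between-subject* basis,
$P_q(a) = m(a) e^{z_q \omega}$: they describe the distribution of
subjects' underlying levels, which is the natural reading of a "normal
range" for an individual child. Because a measured value also carries
assay noise, a *total* basis replacing $\omega$ with
$\sqrt{\omega^2 + \sigma^2}$ is exported as well; with $\sigma$ fixed at
0.2 the band widens only modestly, but the choice is the user's, and both
are written by the pipeline. Percentiles are computed sex-independently.
A seeded Monte-Carlo route (empirical percentiles of simulated
individuals) exists mainly as a cross-check of the closed form and for
future non-lognormal extensions.

The visual predictive check simulates replicate datasets (minimum 100,
default 200) at the observed ages, re-applies censoring at the effective
LLOQ, bins ages into quantile-based bins (default 6; bins with fewer than
3 observations merge into a neighbour, with a message), and compares
observed binned 5th/50th/95th percentiles with the 90% band of each
percentile across replicates, reporting per-level coverage fractions.

## Pipeline, seeds and problem sizes

`run_pipeline()` chains simulate → summarize → screen → fit → centiles/VPC
and writes CSV/JSON artifacts plus a run log; per-stage seeds derive from
the master seed as $(131\,\text{seed} + 7919\,\text{stage}) \bmod
(2^{31}-1)$, so any stage is reproducible in isolation. Outputs contain no
timestamps; identical configs produce byte-identical files (tested). A
failing stage aborts with its name and keeps earlier outputs. The resolved
configuration round-trips through JSON (chosen over YAML for lossless
doubles).

Default analysis sizes follow the emulated study: cohorts of n = 271; the
stochastic operating-characteristic checks in the test suite use 100
replicate cohorts (parameter recovery, model selection), 500 permutations
(type-I error) and 30 meta-replicates of 100-replicate VPCs — sizes at
which the Monte-Carlo error of each check is comfortably below the margin
it asserts.

## Known limitations

* Only lognormal variability: no Box–Cox/power transforms, and no
  age-dependent $\omega$ or $\sigma$.
* No covariates inside the mixed model — covariate effects are screened
  univariately only, as in the analysis this package operationalises.
* The per-condition default treats a subject's conditions as independent;
  the shared-$\eta$ mode is a coarse, single-parameter-family alternative,
  not a full multivariate random-effects structure.
* Centile curves are model-based, not smoothed empirical centiles
  (LMS/GAMLSS are a different method family answering a different
  question).
* With single observations per subject, $\sigma$ must be supplied, and
  misspecifying it shifts $\hat\omega$ (though barely the median curve):
  sensitivity to the fixed value should be checked when adapting the
  default.
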