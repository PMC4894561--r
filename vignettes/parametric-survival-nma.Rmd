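---
title: "Indirect survival comparisons with time-varying hazard ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect survival comparisons with time-varying hazard ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmasurv)
```

## The problem

Two treatments are each compared against the same comparator in separate
randomized trials, but never against each other.  The textbook answer is
the Bucher indirect comparison: divide the two reported hazard ratios and
combine their log-scale standard errors in quadrature.  That answer is
only as good as its proportional-hazards assumption — when the survival
curves of a trial cross, a single HR is a misleading summary, and the
indirect contrast inherits the distortion.

`nmasurv` implements the alternative: reconstruct approximate
patient-level data from the published Kaplan–Meier curves, and fit a
Bayesian parametric survival network meta-analysis in which the hazard
ratio of the indirect pair is a *function of time*.  The motivating use
case is second-line therapy of metastatic renal-cell carcinoma, where a
nivolumab trial and a cabozantinib trial share an everolimus control arm
and one of the trials shows crossing OS curves.

## Model

Monthly interval counts are the likelihood input.  For arm $a$ of study
$s$ and month $j$, with $n_{saj}$ at risk at the month start and
$c_{saj}$ censored during the month,

$$ d_{saj} \sim \mathrm{Binomial}\!\left(n_{saj} - c_{saj},\;
   1 - S(t_{j+1};\theta_{sa})/S(t_j;\theta_{sa})\right). $$

Four families supply $S(t;\theta)$: exponential (rate $\lambda$),
Weibull (rate $\lambda$, shape $k$; $S = e^{-\lambda t^k}$), Gompertz
(rate $\lambda$, shape $\gamma$; $S = \exp\{-(\lambda/\gamma)(e^{\gamma
t}-1)\}$) and log-logistic (scale $\alpha$ = median, shape $\beta$;
$S = 1/(1+(t/\alpha)^\beta)$).  Every positivity-constrained parameter is
modelled on the log scale; the Gompertz shape, which may legitimately be
negative, uses the identity link.

The network structure is fixed-effect: each study contributes a baseline
vector $\mu_s$ (the transformed-scale parameters of its reference arm)
and each non-reference treatment a single effect vector $\delta_k$ acting
additively on the *whole* transformed parameter vector,

$$ \theta_{sa} = g^{-1}\!\left(\mu_s + \delta_{t(a)} -
   \delta_{r(s)}\right), $$

with $\delta = 0$ for the network reference treatment.  Subtracting the
study's own reference-arm effect makes the parametrization invariant to
which arm of a study is labelled its baseline; between-treatment
contrasts are unchanged (this is tested).  Effects act on both parameters
of the two-parameter families — a one-parameter effect would force
near-proportional hazards and defeat the purpose.  Under the exponential
family the effect is exactly a log hazard ratio and the model reproduces
the Bucher assumption; the fitted exponential posterior median HR agrees
with the Bucher point estimate on the same data to within 10% (tested).

Transitivity holds *by construction* at every time point: the HR of
nivolumab vs cabozantinib is, per posterior draw, the ratio of the two
vs-everolimus HRs.  It is asserted to machine precision per draw in the
tests.

Priors are independent Normal(0, sd = 10) on every transformed-scale
parameter — effectively flat over the plausible region (a log-rate of
±30 is astronomically far from any survival data) while keeping the
posterior proper.  The prior sd is configurable.

## Estimation

The sampler is an adaptive random-walk Metropolis scheme: chains start at
the posterior mode (found by BFGS), the initial proposal covariance is
the inverse Hessian at the mode, a Robbins–Monro recursion tunes the
global scale toward 23.4% acceptance, and the empirical covariance of the
burn-in history replaces the Hessian approximation once enough samples
have accumulated.  Starting points are overdispersed by two posterior
standard deviations so the Gelman–Rubin diagnostic retains power.  For
the 4–8-parameter fixed-effect models at hand this mixes well; the
production default is 3 chains × 20,000 iterations with 10,000 burn-in,
while tests and the acceptance script use 3 × 6,000 / 3,000
(log-logistic) and 3 × 3,000 / 1,500 (exponential) to stay inside their
time budgets — at those lengths the maximum PSRF is typically ≤ 1.01.

Convergence is summarized by the classic (non-split) potential scale
reduction factor; `cmd_fit()` refuses to summarize a family whose worst
PSRF exceeds 1.01 unless forced.  Model ranking uses the deviance
information criterion with the deviance evaluated from the full binomial
log-likelihood (combinatorial constant included) and
$p_D = \bar D - D(\bar\theta)$ at the posterior mean on the transformed
scale, which keeps $\bar\theta$ in the admissible region.  Because the
inclusion of the combinatorial constant in the published DIC values is
unknowable, only DIC *orderings* are meaningful targets, never absolute
values.

## Curve inversion (Guyot)

`reconstruct_ipd()` inverts a digitized KM curve plus numbers-at-risk
table deterministically.  Within each interval between risk-table times,
censoring times are spread on an even lattice; their count is adjusted
until the implied at-risk count matches the published table at the next
reporting time; deaths at each digitized step are recovered by rounding
the survival-ratio counts.  Conventions worth stating:

* the number at risk at time $t$ counts patients with observed time
  $\ge t$ — the standard KM convention, and the one that makes the
  simulate → digitize → reconstruct round trip self-consistent;
* risk-table times with no digitized coordinate get a value-preserving
  step point inserted, and risk times beyond the last drop extend the
  curve flat, so late administrative censoring is placed where the table
  says patients were still under observation;
* negative implied censoring (an artifact of integer rounding) is
  clamped to zero with a warning; an at-risk target that cannot be hit
  with zero censoring is adjusted downward, as in the published
  algorithm; a non-convergent adjustment loop raises an error naming the
  offending interval;
* monthly bins are half-open $[m, m+1)$; an event exactly on a boundary
  belongs to the later bin, consistent with right-continuous curves;
* the default 24-month horizon matches the window over which both
  source trials still report patients at risk.

On the default synthetic scenario (400/arm, with censoring) the round
trip reproduces the input curve to within 0.005 absolute survival at
every digitized coordinate and the at-risk table to ±1 patient.

## The synthetic world

Because the source trials' digitized coordinates were never deposited,
the package carries its own stated world: two trials sharing an
everolimus arm, 821 and 658 patients, uniform accrual over 13 and 11
months, administrative cutoff 32 and 25 months, a small exponential
loss-to-follow-up hazard (0.002/month), monthly risk tables, and
log-logistic event times.  The everolimus baseline is (α = 19.6, β =
1.30) — median 19.6 months as reported for the control arm.  The effects
were calibrated *once*, before any test was run, to the stated
qualitative truth: nivolumab (α = 25, β = 1.00; the reported 25-month
median) and cabozantinib (α = 21.05, β = 1.382) make the true
nivolumab-vs-cabozantinib HR cross 1 exactly at month 5, reach 0.65 by
month 24, and favour cabozantinib before the crossing — the pattern the
motivating analysis reports.  Censoring rates per arm are only
qualitatively calibrated (the papers do not report censoring
distributions); accrual-driven administrative censoring reproduces the
thinning risk tables of the real trials.

What a green test establishes: the estimator recovers known effects from
data of this size and censoring structure, the reconstruction inverts
curves of this resolution, and DIC points at the generating family when
hazards cross.  What it does not establish: agreement with the published
HR tables or DIC values, which depend on the authors' undisclosed
digitization and are deliberately not targets.

## Numerical choices

* Gompertz survival uses `expm1` and falls back to the exponential
  formula below |γ| < 1e−12; the γ → 0 limit is tested against the
  exponential at γ = 1e−8.
* Interval death probabilities are clamped to [1e−300, 1 − 1e−12] before
  logs; a non-finite parameter vector short-circuits to log-posterior
  −∞.
* Infinite hazards at t = 0 (Weibull or log-logistic shape < 1) raise
  errors rather than returning Inf.
* Ties in the probability-of-best computation are split equally among
  tied treatments, keeping each grid row an exact partition of the
  draws.
* The at-risk denominator removes all patients censored within the
  interval (conservative); an actuarial half-correction is available as
  `censor_adjust = "half"`.

## Known limitations

Fixed-effect only: with one study per contrast, between-study
heterogeneity is unidentifiable, so no random-effects variant is
offered.  All curves in a model share one family — required for
transitivity of the time-varying HR, but real arms may individually
prefer different shapes.  The Guyot inversion inherits the resolution of
the digitized curve: at monthly risk tables its error is well inside the
tested bounds, but coarser tables would degrade it.  The probability of
best treatment compares survival values pointwise; it is not a
restricted-mean or overall ranking.
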