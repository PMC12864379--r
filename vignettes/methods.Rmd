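---
title: "Modelling phased Frankl-scale trajectories: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling phased Frankl-scale trajectories: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esbafit)
```

## The scientific problem

Pediatric dentists rate a child's behaviour in the chair on the Frankl
scale, an ordinal scale with four levels: definitely negative (`--`),
negative (`-`), positive (`+`), definitely positive (`++`). In a phased
sensory-based dental-care programme (ESBA) for autistic children, each
child is rated at the first visit and again at the end of each of three
programme phases. Two cohorts are distinguished at baseline: children
rated `--` or `-` (initially uncooperative, indicator `init_rating = 0`)
and children rated `+` (initially cooperative, `init_rating = 1`; a
first-visit `++` does not occur in this population and is rejected by the
data layer). *Improvement* is cohort-specific: an initially uncooperative
child improves by reaching `+` or `++`; an initially cooperative child
improves only by reaching `++`.

The package implements the full analysis pipeline for such data: ordinal
regression of the repeated ratings, exhaustive model enumeration with
bootstrap-BIC selection, improvement probabilities with bootstrap
intervals, and marginal-homogeneity testing — plus a synthetic cohort
generator with known ground truth so every stochastic procedure can be
validated end to end.

## The model

The response is the end-of-phase rating $Y \in \{1,2,3,4\}$. The core
model is the cumulative logit (proportional odds) model

$$\operatorname{logit} P(Y \le j \mid x) = \theta_j - x'\beta,
\qquad j = 1, 2, 3,$$

with strictly increasing thresholds $\theta_1 < \theta_2 < \theta_3$ and a
single slope vector $\beta$ shared across the three cumulative logits.
Under this sign convention a positive coefficient shifts probability mass
toward higher (more favourable) categories, so "positive slope = better
behaviour" holds throughout. The modelling rows are the three end-of-phase
assessments per child (phase is a numeric 1–3 predictor; the first visit
enters only through `init_rating`, never as a phase-0 row — conditioning
on baseline through the cohort indicator is what makes the two-predictor
model interpretable per cohort). Categorical covariates use first-level
reference dummy coding.

`pom()` maximizes the multinomial likelihood with BFGS and an analytic
gradient. Thresholds are optimized as
$(\theta_1, \log(\theta_2-\theta_1), \log(\theta_3-\theta_2))$, so
ordering holds by construction; convergence is declared when the gradient
norm falls below `tol` (default $10^{-8}$, up to 500 iterations per
round). Category probabilities are computed in the numerically stable
band form $P(a < Z \le b) =
\sigma(a)\,\sigma(-b)\,(1 - e^{b-a})$, which is exact at infinite cuts
and avoids cancellation when both cumulative probabilities are near 1.
Duplicated design rows are collapsed into case weights before
optimization; row-expanded and count-weighted data therefore give
identical fits (this is tested to $10^{-8}$). The covariance matrix is
the inverse observed information, obtained by numerically differentiating
the negative log-likelihood in the direct $(\theta, \beta)$
parameterization at the MLE.

`confint()` defaults to profile-likelihood intervals: the published
final-model intervals are profile intervals (the default of the standard
ordinal-regression software), and Wald intervals are visibly narrower
here (e.g. 1.67–3.29 instead of 1.72–3.36 for the baseline-indicator
slope). Wald intervals remain available via `type = "wald"`; reported
p-values are two-sided Wald z-tests in both cases.

The unconstrained alternative for testing proportional odds
(`pom_nonprop()`) gives each cumulative logit its own intercept and slope
vector. Monotonicity of the implied cumulative probabilities is *not*
enforced — the test's alternative hypothesis is the unconstrained model —
but parameter values that would make an observed cell probability
non-positive are infeasible for the likelihood, and the optimizer
(BFGS with analytic gradient, warm-started from the proportional fit,
polished by alternating Nelder–Mead/BFGS rounds) stays inside the
feasible region. `lrt_prop_odds()` compares the two fits:
$2(\ell_1 - \ell_0)$ on $2p$ degrees of freedom for $p$ design columns.

## Model selection

The candidate space over the ten study predictors (phase, baseline
indicator, age, gender, delivery type, medication, previous anesthesia,
caries burden dmft, gingival status, plaque index) consists of every
main-effect subset plus, for each subset containing phase and another
predictor $X$, one additional model per choice of a single
phase-by-$X$ interaction: $2^{10} + 9 \cdot 2^8 = 3328$ candidates. This
"at most one interaction, partner among the main effects" rule is the
unique reading under which the published total is achieved, and it is
asserted against a brute-force enumeration for small vocabularies.

Selection uses BIC, $-2\ell + k \log n$ with $n$ the number of
phase-level rows in the fit (the observation-level convention of the
reference software), and the bootstrap one-standard-error rule:

1. draw `B` bootstrap copies of the data (default 2000, reduced in the
   examples below);
2. refit every candidate on every copy and record its BIC; compute each
   model's mean and standard deviation;
3. let $m^*$ minimize the mean BIC and $se$ be the standard deviation of
   its scores; select the most parsimonious model whose mean BIC lies in
   $(\overline{BIC} - se, \overline{BIC} + se)$, breaking parsimony ties
   by lower mean BIC.

Two resampling choices are genuinely open (the source analysis says only
that bootstrap "copies" were drawn); the package's defaults are:
resampling **by child** (all three phase rows move together, preserving
within-child dependence) and **stratified by baseline cohort** (45 + 40
drawn within cohort), which guarantees both cohorts — and hence variation
in `init_rating` — are present in every replicate. Row-level and
unstratified resampling are available behind flags for sensitivity
analysis. During selection all models are fitted on the complete-case
sample for the full vocabulary, so BICs are comparable; after selection,
each model of interest is refitted on the largest sample complete for its
*own* predictors (`refit_complete_cases()`), which is why sparser models
are estimated on more children.

Replicates in which a model is degenerate (an unobserved response
category, a constant design column after resampling, or no convergence)
are excluded from that model's summary and counted; a model invalid in
more than `B/2` replicates is dropped from selection with a warning. This
exclude-and-count policy was chosen over imputing a penalty BIC because a
penalty value would have to be arbitrary and would distort means.

### A note on 1se conservatism under a sparse truth

Validation simulations show a structural property of the 1se rule worth
knowing: when the data-generating truth is itself the sparse model
{phase, init_rating}, that model is usually the minimum-mean-BIC model,
its bootstrap BIC standard deviation (about 20 on study-sized data) often
exceeds the mean-BIC gap (about 16) down to the even sparser
{init_rating}-only model, and the rule then steps down to the sparser
model in a substantial fraction of runs. The same gap (355.8 versus 339.6)
holds on the reconstructed study counts. In the original full-space
analysis the minimum-mean-BIC model was a *larger* model, deep enough that
init-only models stayed outside its one-standard-error interval — which is
how {phase, init_rating} emerged there. The package reports both the
minimum-BIC and 1se choices so this behaviour is visible.

## Improvement probabilities and bootstrap intervals

For a fit containing exactly phase and the baseline indicator, the
improvement probability is $P(Y \ge 3)$ for `init_rating = 0` and
$P(Y = 4)$ for `init_rating = 1`, evaluated at the phase of interest.
Percentile bootstrap intervals (`bootstrap_improvement_ci()`) refit
*only the selected model* on each bootstrap copy — matching the original
procedure, which refitted the already-selected model rather than
re-running selection per replicate — and take the 2.5% and 97.5%
empirical quantiles (type-7 linear interpolation between order
statistics, so a seed reproduces intervals bit-identically) of the
resulting probabilities. All six cohort-by-phase intervals come from one
shared set of refits. The exact published interval bounds depend on
resampling details (unit, stratification, RNG) that are not recoverable,
so they are validated by coverage simulation instead. At the study's
sample size (85 children) the intervals show the slight undercoverage
typical of the percentile method: simulated coverage of the nominal 95%
interval sits near 93–94%, around the lower edge of the 93–97% band the
validation suite checks over 300 seeded replications — so that check can
fall marginally on either side of the band's floor depending on the
seed stream. Larger cohorts remove the deficit (interval width and
coverage behave as expected as n grows, which the suite also checks).

When only the marginal count table is available (as for the built-in
reconstruction), children cannot be linked across phases and the
bootstrap falls back to resampling phase-level rows within cohort;
`reproduce_study()` documents this in its output metadata.

## Stuart–Maxwell test

`stuart_maxwell()` tests marginal homogeneity of a paired 4×4 table with
the quadratic form $d'\hat V^- d$ over the first three categories, using
a Moore–Penrose inverse with degrees of freedom equal to
$\operatorname{rank}(\hat V)$. The generalized inverse matters here: the
cooperative cohort's baseline is concentrated in one category, making
$\hat V$ singular. Some implementations instead always use $K-1 = 3$
degrees of freedom; `df = "nominal"` reproduces that convention (under
which all three cooperative-cohort p-values exceed 0.17, while the
rank convention gives 0.32/0.08/0.14 — either way none is significant at
$\alpha = 0.05$). No continuity correction is applied. The joint
baseline-by-phase table is fully determined by marginal counts only when
the baseline is concentrated in a single category;
`transition_table()` raises an explicit error otherwise, because
marginals do not identify transitions — this is why the uncooperative
cohort's test requires child-level data.

## The synthetic generator

`simulate_cohort()` draws study-shaped cohorts: 45 + 40 children by
default, baseline ratings split 6:39 between `--` and `-` in the
uncooperative cohort, covariates from the published per-cohort marginals,
missingness completely at random at the published per-covariate observed
rates, dmft as a right-truncated (at 11) negative binomial (size 0.8,
mean 4.0 before truncation — chosen so the truncated distribution
reproduces the published quartiles 0/2/5 exactly and the SD of 2.9; the
exact family is an implementation choice, and quartile matching was
preferred over matching the published mean of 3.1, which truncation
pulls to 2.9), and end-of-phase
ratings from the proportional-odds model with default slopes 0.90
(phase) and 2.48 (baseline indicator) and thresholds (−1.60, 1.29, 7.24)
— the final-model estimates, i.e. the study conditions. Ages are drawn
from a discrete 7–12 distribution matching the published mean (≈9.2) and
SD (≈1.5).

Phase ratings are conditionally independent across phases given the
covariates, which is exactly the analysis model's assumption; an optional
child-level normal latent shift (`child_effect_sd`) induces within-child
dependence for stress-testing the child-resampling bootstrap. What the
generator does *not* emulate: informative missingness, treatment-type
pathways, anesthesia referral, or baseline-severity-dependent phase
effects (the last is unknowable from published information). Passing
tests on synthetic data therefore validate the estimation and resampling
machinery under the stated model, not robustness to violations of it.

`scenario_library()` fixes three configurations used by the validation
suite: `sparse` (the default truth), `extended` (adds a positive
no-medication effect 1.29, a negative dmft effect −0.21 and a negative
phase-by-baseline interaction −1.32, mirroring the minimum-BIC model's
composition and signs), and `null` (no effects, for type-I-error checks).

## Numerical choices and degenerate inputs

* Threshold ordering by log-increment reparameterization; BFGS with
  analytic gradient, gradient tolerance $10^{-8}$, max 500 iterations,
  with a warm-started polish round if the first round's gradient norm is
  above tolerance.
* Bootstrap refits collapse each model's design to its distinct
  (covariate pattern, response) cells once and only re-weight cells per
  replicate, and warm-start from the full-data fit of the same model.
* An unobserved response category lets the affected threshold drift; the
  fit is returned but flagged `degenerate`, and the selection and
  interval machinery exclude such replicates.
* Ties in minimum-BIC selection are broken by fewer parameters, then
  canonical enumeration order; the 1se parsimony tie by lower mean BIC.
* Pearson goodness-of-fit (`pearson_gof()`) uses observed covariate
  patterns as cells, df = patterns × 3 − parameters, and warns (rather
  than merging cells) when an expected count falls below a configurable
  floor. On the reconstructed final-model data it gives X² = 19.5 on 13
  df, p ≈ 0.11 — the published p of 0.148 presumably used a different
  (unstated) df convention; both agree the model is not rejected.

## Problem sizes used in the validation suite

The test suite exercises the full pipeline at sizes chosen to make the
Monte-Carlo checks sharp while keeping the default run practical:
parameter recovery and per-logit-convergence at 2 000 children, covariate
marginals at 50 000, interval coverage over 300 replications with
`B = 400`, selection consistency over 20 seeds on a reduced 32-model
space with `B = 200`, and type-I error of the homogeneity test over
2 000 simulated tables.

## Worked example

```{r example}
d <- counts_to_long(esba_phase_counts())
fit <- pom(rating ~ phase + init_rating, data = d)
summary(fit)
round(improvement_prob(fit, 0, 1:3), 4)
lrt_prop_odds(fit, data = d)
```

## Known limitations

* Repeated measures are pooled (no random effects or GEE), matching the
  analysis being implemented; the child-level bootstrap is the only
  concession to within-child dependence.
* Only the logit link is provided; no Bayesian estimation.
* Published bootstrap interval bounds and the minimum-BIC model's
  coefficients (which require unpublished covariate data) are validated
  by property-based simulation, not reproduced digit-for-digit.
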