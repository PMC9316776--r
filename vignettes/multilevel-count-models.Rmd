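---
title: "Multilevel count models for zero-heavy survey outcomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel count models for zero-heavy survey outcomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

National household surveys such as the Demographic and Health Surveys record,
for each mother, the number of infants she has lost before their first
birthday. Three features make this outcome awkward for ordinary Poisson
regression:

* **Excess zeros.** Around 70% of mothers report no infant death — far more
  than a Poisson law with the observed mean would predict.
* **Overdispersion.** The variance of the count clearly exceeds its mean
  (equidispersion is the defining Poisson property).
* **Clustering.** Mothers are nested within regions; outcomes within a
  region are correlated, and covariate effects may vary regionally.

`mlcount` addresses all three at once: six count families crossed with a
two-level random-effects structure, estimated by maximum marginal
likelihood, compared by information criteria, and reported as incidence-rate
and odds ratios.

# The model families

Let $y_{ij}$ be the count for mother $i$ in region $j$, with count-part
covariates $x_{ij}$ and (where applicable) zero-part covariates $z_{ij}$.
All families share the log link for the count mean and the logit link for
any zero/hurdle probability:

$$\log \lambda_{ij} = x_{ij}'\beta + r_{ij}' b_j, \qquad
  \operatorname{logit} \pi_{ij} = z_{ij}'\gamma \,(+\, b_{0j}^{(z)}),$$

where $b_j \sim N(0, \operatorname{diag}(\delta^2))$ are region-level random
effects on the intercept and any declared slopes ($r_{ij}$ is the
corresponding sub-vector of $x_{ij}$).

| family | law |
|---|---|
| `poisson` | $y \sim \text{Pois}(\lambda)$ |
| `nb` | NB2: mean $\mu$, $\operatorname{Var} = \mu + \alpha\mu^2$, shape $\nu = 1/\alpha$ |
| `zip` | $P(0) = \pi + (1-\pi)e^{-\lambda}$; $P(k>0) = (1-\pi)\,\text{Pois}(k;\lambda)$ |
| `zinb` | $P(0) = \pi + (1-\pi)\left(\tfrac{\nu}{\nu+\mu}\right)^\nu$; positives $(1-\pi)\,\text{NB}$ |
| `hp` | $P(0) = \pi$; positives $(1-\pi)\times$ zero-truncated Poisson |
| `hnb` | $P(0) = \pi$; positives $(1-\pi)\times$ zero-truncated NB2 |

Zero inflation and hurdle models answer different questions: in a
zero-inflated model a zero can arise either structurally (probability
$\pi$) or from the count law; in a hurdle model all zeros come from one
binary process and the count law only governs positives. NB2 is used
throughout because its variance function $\mu + \alpha\mu^2$ makes
$\alpha \to 0$ recover the Poisson exactly; the package treats
$\alpha < 10^{-8}$ as that exact limit so the dispersion can be optimised
freely down to the boundary.

# Estimation

The marginal likelihood integrates the random effects out group by group:

$$\ell(\theta) = \sum_j \log \int \prod_{i \in j}
  f(y_{ij} \mid \beta, \gamma, \alpha, b)\;
  N(b; 0, \operatorname{diag}(\delta^2))\, db .$$

* **One random term** (the default random intercept): adaptive
  Gauss–Hermite quadrature. For each group the integrand's mode is found by
  a safeguarded Newton ascent (vectorised across groups, warm-started
  between optimiser steps), the rule is recentred at the mode and rescaled
  by the curvature there, and 15 nodes are applied (`fit_control(n_quad =)`
  raises this; the accuracy tests use 25). Gauss–Hermite nodes come from
  the Golub–Welsch eigendecomposition of the Hermite Jacobi matrix.
* **Several random terms** (intercept plus slopes, or a zero-part
  intercept): a group-wise Laplace approximation — inner mode by `nlminb`,
  curvature by a numerically differentiated Hessian. This matches the
  accuracy/cost trade-off generally accepted for multi-dimensional random
  effects; on shared test data the resulting log-likelihoods agree with an
  independent Laplace implementation (glmmTMB) to a few hundredths.

The optimiser is BFGS over an unconstrained vector: fixed coefficients on
their natural scale, $\log\alpha$, and $\log\delta$ per random term
(so variances cannot go negative, and $\log\delta = -\infty$ is admitted as
the exact zero-variance boundary; an SD below $10^{-6}$ deactivates the
term's integration, which is continuous to machine precision). Gradients
are central finite differences; standard errors come from the inverse of a
symmetric central-difference Hessian of the negative log-likelihood at the
optimum. Dispersion and variance standard errors are delta-method
transforms of the log-scale ones. A singular Hessian yields `NA` standard
errors, never fabricated values, and the convergence flag and gradient norm
are stored on the fit.

**Starting values** (documented, conventional): count part from a Poisson
fixed-effects GLM; hurdle zero part from its logistic GLM (which is that
sub-model's exact MLE); zero-inflation intercept from the logit of the
observed zero excess over the Poisson-implied zero fraction; $\alpha$ from
the method-of-moments ratio $(s^2 - \bar y)/\bar y^2$; every random-effect
SD at 0.3.

**Numerical safeguards.** All six pmfs are evaluated in log space: mixture
zeros by log-sum-exp, truncation by $\log(1 - e^{x})$ computed through
`expm1`/`log1p` on the appropriate side of $\log 2$. Non-finite values met
during exploratory optimiser steps (e.g. a grossly misspecified family
pushed to extreme predictors) are treated as downhill rather than fatal.

# Inference and comparison

Wald tests use $z = \hat\theta / \widehat{SE}$ with two-sided normal
p-values and 0.05/0.01/0.001 stars; no multiplicity adjustment is applied,
matching standard reporting for this kind of table. Model ranking uses
deviance $=-2\ell$, AIC $=-2\ell + 2k$ and BIC $=-2\ell + k\log n$ with $n$
the number of mothers, not regions — inverting a published criteria row for
this class of analysis ($k = (AIC - dev)/2 = 35$,
$n = e^{(BIC-dev)/k} \approx 10{,}548$) confirms that convention.
Non-converged fits are listed but can never be selected "best". Count-part
coefficients exponentiate to incidence-rate ratios and zero-part
coefficients to odds ratios of a structural zero, with Wald intervals
formed on the coefficient scale and then exponentiated.

# The synthetic-data generator

`simulate_counts()` draws, in order: covariates (categorical by declared
probabilities, continuous normal), one normal random effect per declared
variance per group, then outcomes from the configured family — structural
zeros first for `zip`/`zinb`, hurdle crossing then an inverse-CDF draw from
the zero-truncated law for `hp`/`hnb`. A single integer seed drives R's
Mersenne–Twister (inversion for normals), so identical (config, seed) pairs
are byte-identical.

`edhs_like_default()` packages a truth emulating a 2016 national survey of
10,547 mothers in 11 regions: the exact unequal region sizes (460 to
1,569), a ZINB outcome, and covariates (residence, mother's age, age at
first birth, birth weight, breastfeeding, birth order, household size)
whose effects carry the signs and magnitudes reported for that survey. The
two intercepts are the one calibrated choice: the published intercepts are
only meaningful together with that survey's full 25-coefficient covariate
profile, so the count-part intercept (3.28, absorbing the centring of the
raw-scale continuous covariates) and the published zero-part intercept
(−1.345) were set so the marginal outcome reproduces the survey's shape —
roughly 72% zeros, mean near 0.53, variance well above the mean. With the
default seed the simulated zero fraction is ~0.72 and the variance/mean
ratio ~3; the ratio runs above the survey's printed 1.88 because the
generator's covariate heterogeneity is continuous and independent, which
fattens the right tail relative to the real (bounded, correlated)
covariates.

**What passing tests do and do not show.** The generator gives every stage
a no-download test surface with known truth: recovery and selection
experiments demonstrate that the estimator is consistent and the criteria
pick the generating family *under the generator's assumptions* —
independent covariates, exactly normal diagonal random effects, no survey
weights, no two-stage cluster sampling, no nonresponse. Real survey
analyses violate all of these to some degree; passing tests validate the
machinery, not any substantive claim about real data.

# Validation problem sizes

The test suite's simulation experiments use sizes chosen to make the Monte
Carlo answer decisive at desk scale: quadrature accuracy against
brute-force grid integration on 20+ random small instances (3 groups × 8);
parameter recovery over 50 seeded ZINB replicates of 40 groups × 100
mothers (observed: per-coefficient mean bias ≤ 4%, pooled 95% CI coverage
0.96); family selection over 20 seeded replicates of 30 groups × 100, where
ZINB's AIC win rate is 20/20. The end-to-end acceptance script fits all six
families to one full-size (10,547-row) synthetic survey.

# Known limitations

* Random effects are independent (diagonal covariance); correlated
  intercept–slope structures are out of scope.
* Multi-dimensional integrals use Laplace, which can understate variance
  components when groups are tiny; raise `n_quad` only for 1-D structures.
* Zero-part coefficients in zero-inflated models are weakly identified
  when the count mean is small; expect wide intervals at modest sample
  sizes (the recovery experiment's gamma SEs illustrate this).
* No survey weights: the fit is unweighted, and descriptive moments of a
  weighted survey will differ slightly from the package's unweighted ones.
* Logit link only for the zero/hurdle part.
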