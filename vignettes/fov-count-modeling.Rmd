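---
title: "Mixed-model selection and power analysis for field-of-view cell counts"
author: "fovpower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model selection and power analysis for field-of-view cell counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fovpower)
```

## The problem

Immunohistochemistry markers such as Ki67 are scored by counting positively
and negatively stained cells in several microscope fields-of-view (FoV)
across each tissue section. Tissue is heterogeneous: the positivity
fraction varies from FoV to FoV within a sample, from sample to sample
within a patient, and from patient to patient. Treating the cells of a
sample as one big binomial draw ignores this clustering and overstates the
information in the data, which matters both when estimating a treatment
effect and when deciding how many FoVs and how many cells per FoV to count.

`fovpower` addresses both tasks. It fits mixed-effects models to FoV-level
count tables under six candidate error distributions and compares them by
AIC, and it estimates, by simulation, the power of a planned design as a
function of the number of FoVs per sample and cells counted per FoV.

## The model

For FoV $r$ of sample $j$ in individual $i$, let $k_{ijr}$ of $m_{ijr}$
counted cells be positive. The linear predictor is

$$\eta_{ij} = \beta_0 + \beta_t\,\mathrm{treat}_{ij} +
  \beta_{b(ij)} + u_i + v_{ij},\qquad
  u_i \sim N(0, \sigma_u^2),\; v_{ij} \sim N(0, \sigma_v^2),$$

with treatment and assessment batch as fixed effects and random intercepts
for sample nested within individual. The six error families are

* **binomial** and **beta-binomial** on the logit scale for
  $(k, m)$ jointly; the beta-binomial mixes the FoV-level positivity over a
  $\mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ law, giving intra-FoV correlation
  $\rho = 1/(\phi+1)$ and variance
  $m\mu(1-\mu)\{1 + (m-1)\rho\}$;
* **Poisson**, **generalized Poisson** (variance $\mu\phi$, $\phi \ge 1$),
  **NB1** (variance $\mu(1+\alpha)$) and **NB2** (variance
  $\mu + \mu^2/\theta$) on the log scale for $k$ alone, with
  $\log m$ as an offset.

Families are compared on the same data by AIC
($-2\ell + 2p$, where $p$ counts fixed effects, the two variance
components, and the dispersion parameter if the family has one), and the
model-implied mean percent positivity per arm is reported for the average
subject (random effects at zero), both at the reference batch and averaged
over batches.

### Parameterization choices

The literature names these families but rarely pins down a
parameterization, so the package declares its own and sticks to it:

* Generalized Poisson uses the mean/variance form
  $\mathrm{Var} = \mu\phi$, internally $\theta = \mu/\sqrt\phi$,
  $\lambda = 1 - 1/\sqrt\phi$,
  $P(k) = \theta(\theta + \lambda k)^{k-1} e^{-\theta - \lambda k}/k!$.
  This keeps the mean scale shared across families so AICs are comparable.
  Underdispersion ($\phi < 1$) is rejected rather than supported: it
  truncates the support and never arises in immunostaining counts.
* The beta-binomial is parameterized by the precision $\phi$ rather than
  $\rho$; the binomial limit $\phi \to \infty$ is then clean.
* NB1 is the size $= \mu/\alpha$ reparameterization of the standard
  negative binomial, the usual device for a linear mean-variance
  relationship.

## Likelihood and fitting

The marginal likelihood integrates the random effects out per individual.
The package uses the **Laplace approximation**: for each individual the
joint mode of its $1 + J$ random effects is found by damped Newton
iterations (the Hessian has arrow structure and is solved in $O(J)$), and
the Gaussian curvature correction $-\tfrac12\log\det H$ is added. Dense
Gauss–Hermite quadrature would be more accurate but scales exponentially
in $J$; it is retained in the test suite as an oracle on tiny instances,
where the two agree to better than 0.05 on the log-likelihood scale.

Numerical choices that matter:

* The inner mode search declares convergence on the **Newton decrement**
  rather than the gradient norm or objective decrease. When
  $\sigma_v$ collapses towards zero the prior precision $1/\sigma_v^2$
  makes absolute gradient tolerances unattainable, and near the mode the
  objective changes by less than double precision can resolve. The
  decrement is scale-invariant and is driven to $10^{-15}$; because the
  $\log\det H$ term depends on the mode to first order, anything looser
  leaves noise in the outer objective that corrupts finite-difference
  derivatives.
* The outer maximization runs `nlminb` on the packed vector
  (fixed effects, $\log\sigma_u$, $\log\sigma_v$, log dispersion;
  $\log(\phi-1)$ for the generalized Poisson). Variance components are
  optimized on the log-SD scale with a floor at $10^{-8}$; fits ending on
  the floor are reported as zero variance. Starting values come from a
  dispersion-free fixed-effects IRLS fit, SDs start at 0.3, and dispersion
  at a method-of-moments guess — all deterministic.
* Standard errors come from the inverse of a central finite-difference
  observed-information matrix with step $10^{-4}(1+|\theta|)$. A smaller
  step ($10^{-5}$) was measured to amplify the residual $\sim 10^{-9}$
  evaluation noise of the Laplace objective enough to distort the inverse;
  at $10^{-4}$ the treatment-coefficient standard error agrees with an
  independent implementation (glmmTMB) to a few tenths of a percent.
  Parameters pinned at a bound, or whose direction has vanishing
  curvature (a variance component collapsing to zero), are profiled out
  and reported with `NA` standard errors.
* FoVs of the same sample with identical counts contribute identical
  likelihood terms, so rows are aggregated with multiplicity weights
  before fitting. This is exact and purely computational.

Non-convergence is reported through `converged = FALSE`, never an
exception, so simulation loops can tally it.

## The synthetic-data generator

No patient-level data ship with the package, so `simulate_dataset()`
stands in for them. It draws the hierarchy the model assumes: Gaussian
individual and sample intercepts on the link scale, then FoV-level counts
from the chosen family. The default generative truth is

| parameter | default | meaning |
|---|---|---|
| `beta0` | `qlogis(0.30)` | 30% baseline positivity |
| `beta_treatment` | `-0.2` | logit-scale treatment shift (about -4 percentage points from 30%) |
| `beta_batch` | none | no batch effects in simulation |
| `sd_individual` | 0.5 | between-patient SD, logit scale |
| `sd_sample` | 0.1 | between-sample SD within patient |
| family | beta-binomial, `phi = 3` | intra-FoV correlation 0.25 |

The study design defaults to 25 individuals, each with a paired control
and treated sample, in a single batch. The fitted variance components of
the motivating patient cohort were never published, so the SDs and
dispersion above are declared, realistic stand-ins chosen once: a
between-patient SD of 0.5 on the logit scale spans roughly 20–45%
positivity across patients, sample pairs from one tumor agree much more
closely (SD 0.1), and $\rho = 0.25$ is typical of the strong FoV-to-FoV
heterogeneity seen in explant sections. They are defaults, not constants —
every simulation entry point accepts its own `sim_params()`.

Log-link count families draw from the count distribution with mean
$m\,e^\eta$ and redraw the rare values exceeding the FoV total (a counter
is attached to the dataset); these families exist mainly as analysis
models for real data, not as generators.

What the generator does **not** emulate: spatial structure among FoVs,
unequal cells per FoV within a sample (supported but not defaulted),
missing or necrotic FoVs, and batch-by-treatment confounding. Passing
tests therefore demonstrate correctness of the machinery under the stated
hierarchy, not robustness to every artefact of real slides.

## The power study

`run_power_grid()` loops over a grid of (FoVs per sample) x (cells per
FoV). Each replicate simulates a dataset under the generative truth, fits
the analysis model (beta-binomial by default, batch omitted since the
simulated design has one batch), and applies a two-sided **Wald z-test**
to the treatment coefficient at $\alpha = 0.05$. The detection rule is a
declared choice: with 25 individuals the z reference is slightly
anti-conservative compared to a t-type correction, which is the familiar
behavior of maximum-likelihood mixed models in this software family.

Power is reported as rejections over **converged** fits; failures are
counted and surfaced (`unreliable` flags cells with more than 20%
failures), so the pessimistic convention (failures as non-rejections) can
be recomputed from the same table. A Wilson 95% interval quantifies the
Monte-Carlo error — Wilson rather than Wald because it behaves near 0 and
1. Replicate seeds are derived from (master seed, FoV count, cell count,
replicate index) by a counter-based hash, so any subset of the grid, in
any execution order, reproduces the same numbers.

A reference-scale run uses 2000 replicates per cell; the package defaults
its own checks to 300 replicates per anchor cell (Monte-Carlo SE about
2.3 percentage points near 80% power) and 50 for robustness sweeps, which
keeps a full verification inside desk-scale runtimes.

## Known limitations

* The Laplace approximation is least accurate for small cluster sizes
  with strong overdispersion; the quadrature oracle bounds the error on
  tiny instances only.
* REML-type small-sample corrections and likelihood-ratio or bootstrap
  tests are out of scope; Wald at $\alpha = 0.05$ is the only detection
  rule.
* Random slopes, crossed random effects, and zero-inflated families are
  not supported.
* The generalized Poisson is restricted to overdispersion
  ($\phi \ge 1$).
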