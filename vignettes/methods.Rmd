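---
title: "Testing for treatment effects with NLMEM: models, approaches and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for treatment effects with NLMEM: models, approaches and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlmetrt)
```

## The problem

Longitudinal trial data analysed with nonlinear mixed-effects models
(NLMEM) give high power to detect treatment effects, but the likelihood
ratio test (LRT) that usually drives the decision assumes the null model is
correctly specified. With real natural-history data that assumption always
fails to some degree, and the failure is not benign: a drug model added to
a misspecified placebo model can soak up unexplained structure in *both*
arms, producing enormous spurious likelihood gains and type I error rates
approaching 100%. `nlmetrt` implements seven testing approaches that
navigate this problem in different ways, a synthetic cohort generator whose
misspecification is under the user's control, and a replicate-trial battery
that measures type I error, power, and the accuracy (RMSE) of the
treatment-effect estimate.

## Models

**Placebo (disease) model.** The published disease model for an
ADAS-cog-like score is linear in time with the baseline driven by a
baseline Mini-Mental State (BMMS) covariate:

$$y_{ij} = (\theta_{base} + \theta_{int}\,BMMS_i + \eta_{1i})
         + (\theta_{slp} + \theta_{slp,b}\,BMMS_i + \eta_{2i})\,t_{ij}
         + \varepsilon_{ij},$$

with $\eta_{ki} \sim N(0, \omega_k^2)$ and
$\varepsilon_{ij} \sim N(0, \sigma^2)$: 7 estimated parameters. The
original covariate function on the slope is published elsewhere and not
reproduced here; a slope linear in BMMS is used as a structural stand-in.

**Alternative placebo models** (used by the placebo-and-drug model
averaging approach), each adding one parameter: a time-exponential
progression $(\exp(\theta_r t) - 1)/\theta_r$ in place of $t$ (reduces to
the linear model as $\theta_r \to 0$); inter-individual variability on the
residual error magnitude ($\sigma_i = \sigma e^{\eta_{3i}}$); a Boxcox
transform of the baseline random effect
($(\exp(\lambda\eta_1) - 1)/\lambda$, identity as $\lambda \to 0$); and a
scaled-t distributed baseline random effect (Gaussian as
$\nu \to \infty$). The exact functional forms of these alternatives are
standard pharmacometric choices, declared here rather than inherited from
any single reference.

**Drug models.** Offset: adds $\theta_{DE} (+\eta)$ at $t > 0$ (the
baseline measurement precedes randomization, so the effect applies
post-baseline only — a declared choice, configurable). Time-linear: adds
$(\theta_{DE} (+\eta))\,t/36$, so the typical effect at month 36 equals
$\theta_{DE}$; the printed form of this model is ambiguous and is resolved
this way so that "typical effect at the end of the study" has its plain
meaning. Disease-modifying: multiplies the subject's slope by
$1 - (\theta_{DE} + \eta)$, so $\theta_{DE} = 1$ arrests progression. IIV
on the effect adds one variance parameter.

## Likelihood computation

NONMEM's FOCE approximation is replaced by exact computation where exact
computation is possible. Every model above except three is *linear in its
Gaussian random effects*, so the subject-level marginal likelihood is the
closed-form multivariate normal density
$y_i \sim N(X_i\beta,\; Z_i\Omega Z_i' + \sigma^2 I)$. Model fitting
profiles $\beta$ and $\sigma^2$ out by generalized least squares and
searches only over variance ratios (plus any structural nonlinear
parameter), which makes a fit a 2–4-dimensional optimization.

The three exceptions — disease-modifying with IIV (a product of two random
effects), IIV on the residual error, and the Boxcox/t-distributed baseline
effects — use a Laplace approximation of each subject's marginal
likelihood around the empirical-Bayes mode. Two implementations exist:

* a specialised kernel for the published placebo + disease-modifying-IIV
  model (the only non-linear model on the hot path of the evaluation
  batteries), which profiles the two linear random effects exactly in
  closed form and performs a guarded 1-D Newton search over the drug
  effect, all on per-subject sufficient statistics;
* a generic per-subject Laplace for everything else, run in
  prior-standardized coordinates so that near-degenerate variance
  components do not stiffen the inner problem.

The generic path is also callable on linear models
(`marginal_ofv(..., method = "laplace")`), where Laplace is exact; the test
suite uses this as an oracle-equivalence check (agreement to $10^{-6}$
relative), and cross-checks the specialised kernel against the generic
path.

Mixture models (for individual model averaging) combine the two component
likelihoods per subject,
$L_i = \pi_{1i} L_i^{plb} + (1 - \pi_{1i}) L_i^{plb+drug}$, with
arm-dependent $\pi_{1i} = (1 - TRT_i)\,\theta_{MIX} + TRT_i\,(1 -
\theta_{MIX})$.

### Numerical choices

* Variances are optimized on the log scale (floor $10^{-10}$), the mixing
  probability on the logit scale.
* The transformed coordinates are rescaled once per fit by the inverse
  square root of the diagonal curvature: the covariate-by-time fixed
  effect has a curvature about $10^6$ times the baseline's, which would
  otherwise cripple the quasi-Newton search.
* Convergence requires a finite OFV and a projected-gradient infinity norm
  below 0.5–1 on the scaled fitting scale (bound-active coordinates are
  projected out). A strict $10^{-5}$ gradient norm is unattainable with
  numerically differenced objectives of magnitude $10^3$–$10^4$; the
  chosen tolerance corresponds to sub-0.01 OFV resolution, far below the
  3.84 LRT granularity. Stalled quasi-Newton runs ("false convergence")
  are polished with a simplex search and re-descended before a fit is
  declared failed.
* Failed fits are excluded from all rate computations and counted,
  mirroring the removal of runs with failed minimization status in the
  original evaluation; exclusions are reported per trial.
* AIC ties between candidates go to the first-listed candidate; candidate
  order is part of the configuration.
* The empirical cutoff of cLRT/rcLRT is the plain type-7 quantile of the
  null dOFV draws; an $(r+1)/(n+1)$ randomization-test variant is
  available (`rule = "r_plus_1"`).
* Akaike weights are $\exp(-\Delta AIC/2)$, normalized. (The source
  publication prints the weight formula without the $-1/2$ factor, which
  would give the *worst* model the largest weight and contradicts its own
  reported $10^{-24}$ null-model weights; the standard formula is
  implemented.)
* RMSE takes the square root (the printed formula omits the radical but
  reports magnitudes on the root scale) and divides by the number of
  non-excluded trials.
* One permutation-specific exactness: the placebo model's likelihood does
  not involve the allocation, so the observed placebo fit is reused across
  permutation replicates. This is an identity, not an approximation.

## The seven approaches

| id | null hypothesis | alternative | decision rule |
|----|-----------------|-------------|---------------|
| STDs | placebo | placebo + drug (treated arm), best of the candidate set by AIC | $\chi^2$ LRT, df = extra parameters |
| SSs | placebo + drug fitted to *all* subjects | arm-specific drug parameters | $\chi^2$ LRT, df = duplicated parameters |
| cLRT | as STDs | as STDs | empirical cutoff from cohorts simulated under the fitted H0 |
| rcLRT | as STDs | as STDs | empirical cutoff from permuted allocations |
| MAD | placebo | all drug candidates | total Akaike weight of the alternatives (no test) |
| MAPD | all placebo models | placebo × drug grid | as MAD |
| IMA | mixture, $\theta_{MIX} = 0.5$ fixed | mixture, $\theta_{MIX}$ estimated arm-dependently | $\chi^2$ LRT, 1 df |

For IMA the drug component applies within the second mixture component
regardless of arm, so the *null* already contains the drug model — the
test is purely on whether the component allocation follows the treatment
arms. Its effect estimate is
$(2\hat\theta_{MIX} - 1)\hat\theta_{DE}$, which is exactly 0 at the null
allocation rate. The IMA alternative's likelihood is flat in
$\theta_{MIX}$ when the fitted drug effect is near zero; such flat-ridge
optima are legitimately converged (dOFV $\approx$ 0, retain).

For the model-averaging approaches a trial contributes its H1 weight
fraction to the battery-level rate (the "average of the percentage of
relative weights" convention), rather than being thresholded.

## The synthetic cohort generator

The generator emulates the structure of an ADNI-like natural-history
cohort: 817 subjects by default, visits at 0, 6, 12, 18, 24, 36 months,
BMMS $\sim N(25, 2.5^2)$, baseline $= 65 - 1.8\,BMMS$ (about 20 ADAS-cog
points at BMMS 25), slope $= 0.75 - 0.02\,BMMS$ points/month (about 3
points/year), $\omega^2_{base} = 25$, $\omega^2_{slp} = 0.02$,
$\sigma^2 = 9$. These defaults are chosen once for ADAS-cog plausibility —
the published model's exact estimates are not public in the source and are
not claimed. Scores are treated as continuous and not clipped to [0, 70]
by default (a clipping flag exists). Complete data are generated by
default; a missing-at-random dropout rate of about 0.32 reproduces the
observation density of the motivating dataset (3597 of 4902).

**The latent misspecification component** is the generator's stand-in for
real-data placebo-model misspecification: an additive subject-level term
$\gamma_i (t/36)^p$ with $\gamma_i \sim N(\mu_\gamma, \tau_\gamma^2)$,
default $p = 2$, $\mu_\gamma = \tau_\gamma = 10$ points. The magnitude was
calibrated once, before any battery was run to completion, by the stated
rule that the single-fit dOFV impact of the best drug candidate on a
no-effect cohort must greatly exceed the $-5.99$ LRT cutoff: at 150
subjects the defaults give single-fit dOFVs of about $-12$ to $-40$,
consistent per subject with the $-133$ observed on the motivating
817-subject dataset. It was then frozen. Because much of a quadratic
trend is absorbed by the placebo model's random baseline and slope, the
component must be large in raw units to leave this much unexplained
structure; its visible signature is a fan of accelerating trajectories.

What a green battery does and does not establish: the generator produces
Gaussian random effects, a smooth convex latent term, complete balanced
data and arm-exchangeable misspecification. Real natural-history data
misspecify in rougher ways (heavy tails, floor/ceiling effects, informative
dropout). The rcLRT calibration result is insensitive to this by
construction (permutation exchangeability); the IMA result is not, and its
control here is evidence within this stated world, not a theorem.

A side effect worth knowing: under the misspecified generator the
treatment-effect estimates of all approaches are biased low by roughly 2
points at an injected 8-point offset (the latent curvature loads
asymmetrically once the treated arm has an extra regressor), so battery
RMSEs are dominated by this bias rather than by noise. Power is
unaffected.

## Evaluation battery

`run_battery()` repeats generate → randomize 1:1 → (inject effect) → test
for N trials, with all seeds derived from a master seed through a
counter-based scheme (`child_seed`), so any single trial is reproducible
in isolation. Type I error and power are rejection frequencies over
non-excluded trials; the acceptance region for a nominal 5% level is the
exact (Clopper–Pearson-type) binomial interval around the expected count —
for N = 100 this is the printed 1.64–11.28%.

The engine-calibration check deliberately uses a *single* 1-df drug
candidate on a correctly specified generator: with no selection step, no
boundary parameter and no misspecification, the dOFV is asymptotically
$-\chi^2_1$ and the rejection rate must sit in the binomial region. This
isolates LRT calibration of the likelihood machinery from the
selection-induced and misspecification-induced inflation that the
approach-level batteries measure.

## Known limitations

* Balanced two-arm designs only; no dose–response, no >2 arms, no
  unbalanced allocation.
* Estimation provides no standard errors (none of the approaches needs
  them); uncertainty statements come from replicate batteries.
* The Laplace approximation differs from FOCE; agreement with
  NONMEM-estimated OFVs is expected only up to the usual
  approximation-level differences.
* The generic Laplace path (Boxcox, t-distribution, residual-error IIV
  placebos) is orders of magnitude slower than the closed-form path and is
  intended for the model-averaging grid on moderate cohorts, not for
  permutation batteries.
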