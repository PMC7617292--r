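---
title: "Latent-profile-moderated mediation over latent growth curves: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-profile-moderated mediation over latent growth curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modmedgrowth)
```

## The scientific question

Two-arm relapse-prevention trials in recurrent depression — mindfulness-based
cognitive therapy with antidepressant-tapering support versus maintenance
antidepressants — leave open *for whom* and *through what mechanism* the
psychological arm works. `modmedgrowth` implements the secondary analytic
chain used to address that question:

1. **Latent profile analysis (LPA)** over a baseline battery of
   clinical-severity indicators identifies subgroups ("lower" versus "higher
   severity of depression history").
2. **Latent growth curve models (LGCM)** summarise each participant's
   six-occasion BDI-II series (months 0, 3, 9, 12, 18, 24) by latent
   intercept, linear-slope and quadratic factors, estimated by
   full-information maximum likelihood (FIML) under missingness at random.
3. **A moderated-mediation model** asks whether trial arm changes
   mindfulness skills (FFMQ change score, the *a*-path), whether that change
   drives the linear rate of symptom change (the *b*-path), and whether the
   mediated pathway differs between the latent profiles (the index of
   moderated mediation), with percentile-bootstrap confidence intervals.

## Model details

### Latent profiles

The indicator battery mixes continuous scores (residual symptoms, abuse
history, rumination, positive affect, ...) and one binary item (previous
suicide attempt). The mixture assumes local independence given class,
class-specific means for continuous indicators with class-invariant
variances, and class-specific Bernoulli probabilities bounded away from
\{0, 1\} by $10^{-4}$. Missing indicator entries contribute through the
casewise product over observed entries, consistent with the FIML treatment
elsewhere in the chain. Estimation is EM from `n_starts = 20` random
initialisations (tolerance $10^{-6}$ on the relative log-likelihood change,
at most 500 iterations); the per-iteration log-likelihood trace is stored so
monotonicity is checkable on every fit. Classes are relabelled in ascending
order of the first symptom-intensity indicator, which makes output
deterministic given the seed. Model selection tabulates AIC, BIC, relative
entropy $1 - \sum_{ik}(-p_{ik}\log p_{ik})/(n\log K)$ and the smallest class
fraction for $K = 1,\dots,K_{\max}$, flagging the BIC minimiser. Class-varying
variances, within-class covariances and three-step (BCH-style)
classification-error corrections are deliberately out of scope in this
version; classification is modal and labels are treated as known downstream.

### Latent growth curves

With occasions $\lambda_t \in \{0,3,9,12,18,24\}$ months, the quadratic
model is $y_{it} = \eta_{0i} + \eta_{1i}\lambda_t + \eta_{2i}\lambda_t^2 +
\varepsilon_{it}$, mean structure $\Lambda\alpha$, covariance
$\Lambda\Psi\Lambda^\top + \Theta$. Residuals may be homoscedastic (one
$\theta$), heteroscedastic (six free $\theta_t$), or heteroscedastic with a
lag-power autocorrelation $\Theta_{jk} =
\sqrt{\theta_j\theta_k}\,\rho^{|j-k|}$ over the *occasion index* (a
month-gap exponent is available via `ar_on_months = TRUE`). The FIML
log-likelihood sums, per case, the multivariate-normal log-density over that
case's observed occasions; cases are grouped by missingness pattern and the
kernel is evaluated in compiled code.

Numerical choices: the quadratic loading column is scaled by $1/100$
internally (raw $\lambda_t^2$ reaches 576 and conditions the optimisation
badly) and estimates are reported back in points/month²; $\Psi$ is
parameterised through its Cholesky factor with log-transformed diagonal,
$\theta_t$ are log-transformed and $\rho$ tanh-transformed, so the implied
covariance is positive semi-definite at every iterate; optimisation is
quasi-Newton (`nlminb`) from a moment-based start plus jittered restarts.
Factor variances whose estimates hit the effective lower bound are reported
as boundary solutions; one-sided Wald tests of variance are provided with
the usual caveat that they are conservative at the boundary, and any factor
variance can be fixed to zero by specification. Nested model comparisons use
likelihood-ratio tests (df = parameter-count difference) alongside AIC/BIC.

### Moderated mediation

With groups $g$ from the LPA stage, exposure $X$ (arm, 0/1) and mediator $M$
(FFMQ change):

$$M = a_{0g} + a_g X + \gamma_{Mg}^\top z + e_M, \qquad
\eta_1 = \beta_{10g} + b_g M + c'_g X + \gamma_{Sg}^\top z + \zeta,$$

with the quadratic measurement structure retained for the outcome series but
only the linear slope used as the structural outcome. $(M, y_1,\dots,y_6)$
are jointly normal given $X$, $z$ and group, so the model is estimated by
the same pattern-based FIML kernel; the implied cross-covariance is
$\mathrm{Cov}(M, y_t) = b_g\sigma_{Mg}^2\lambda_t$. Conditional indirect
effects are $\mathrm{IE}_g = a_g b_g$ and the index of moderated mediation
is $\mathrm{IE}_2 - \mathrm{IE}_1$ (equal to $(a_2-a_1)b$ under a shared
*b*). The total effect $c$ comes from refitting without the mediator.
Defaults mirror a final model in which only the *a*-path is moderated:
$b$ and $c'$ shared across groups, with the freely moderated fit also run to
supply Wald moderation tests. Residual $\theta_t$ and $\rho$ are shared
across groups for parsimony. Coefficients stay in raw units (FFMQ points;
BDI-II points/month). No multiple-testing correction is applied, matching
the exploratory character of such secondary analyses.

Inference for products of coefficients uses the nonparametric percentile
bootstrap (default $B = 1000$), resampling cases within arm strata,
refitting from the full-sample solution as warm start, and taking the
$(B+1)\alpha$-th order statistics of the draws as bounds; an effect is
flagged significant when zero lies outside its interval. Labels are held
fixed under resampling, so classification uncertainty is not propagated — a
documented limitation of the classify-then-analyse linkage. Sensitivity
analyses re-enter home-practice level (a single ordinal 0–3 score) and
antidepressant discontinuation as group-specific linear terms in both
equations.

## The synthetic-trial generator

Patient-level data from such trials are typically available only on request,
so the package ships a generator whose defaults reproduce the published
structure of a 424-participant trial: two latent classes (mixing proportion
0.5 — class sizes are not published, so the split is an even default),
baseline symptom means 10.71 / 19.37 BDI-II points, linear slope −0.30
points/month and quadratic 0.01 points/month², conditional *a*-paths 5.03 /
13.87 FFMQ points, shared *b* = −0.03, direct effect 0.37, and follow-up
retention 82.1 / 69.1 / 76.4 / 68.6 / 79.3 percent. Observed BDI-II scores
are rounded to integers and clipped to the instrument range [0, 63] at the
observation step only; missingness is applied per wave with retention on the
logit scale shifted by arm and standardized baseline score, i.e. genuinely
MAR rather than MCAR, with marginal rates within about half a percentage
point of the configured targets. The post-treatment FFMQ is masked at the
month-3 retention rate so the mediator also exercises the FIML machinery.

Quantities the publication does not print were fixed once at realistic
values and are deliberate design choices, not estimates: mediator
disturbance SD 10 (FFMQ change-score spread), slope disturbance SD 0.12
points/month, intercept variance 16, residual variances 10–14 with
$\rho = 0.3$, and an indicator battery separated by 0.6–0.95 pooled SD per
item (the published profile contrasts are "moderate to large"). Two numbers
deserve comment. First, the printed path coefficients together with any
realistic mediator spread imply substantial slope dispersion through $bM$,
so some floor-censoring at BDI-II = 0 is unavoidable; the chosen defaults
keep the clipped fraction near 3–4% of observations (computed from normal
tail probabilities at design time). Second, with these values the model's
slope-equation $R^2$ is larger, and the mediator-equation $R^2$ for the
high-severity class larger, than the published 10% / 15%: matching those
$R^2$ values exactly would require a slope disturbance SD near 1.5
points/month, which sends a large share of simulated trajectories outside
the instrument range. Fidelity to the printed *path coefficients and
retention* was preferred; the $R^2$ mismatch is a known, documented
discrepancy of the generator. The severity-battery means/SDs, FFMQ baseline
distribution, and practice/discontinuation rates follow the published
descriptive percentages where available.

One consequence of emulating instruments worth knowing: truncation and
rounding (the episode-count floor, the 5–9 severity range, integer scores)
make even the generator's one-class limit detectably non-normal, and at
n = 1000 BIC will prefer a two-component fit to such data. This is correct
behaviour of the mixture machinery, and a useful reminder that in real
batteries "classes" can partly reflect instrument floors and ceilings;
BIC-consistency checks in the test suite therefore use the untruncated
one-class limit.

What passing tests on this generator do **not** show about real data:
indicators are conditionally independent within class (real batteries
correlate within class), the mediator is normal (real change scores are
bounded), missingness is exactly MAR, and there is no therapy-group
clustering. Results on real trials can differ for any of these reasons.

## Verification strategy and problem sizes

The test suite checks each layer against an independent route: the compiled
FIML kernel against a plain-R casewise likelihood and against numerical
integration of a marginalised coordinate; the LPA against a direct
evaluation of the mixture likelihood and against `mclust`'s equal-variance
diagonal model; implied growth moments against Monte-Carlo moments of
$10^6$ directly simulated trajectories; the structural coefficients against
ordinary least squares in the near-noise-free limit where latent slopes are
observable; and the bootstrap against the closed-form interval for a sample
mean. FIML on complete data is required to coincide (sup-norm $10^{-6}$)
with an independently coded complete-data likelihood optimised from the
same point.

Calibration experiments use sizes chosen to make Monte-Carlo error small
relative to the assertion while keeping the default test run quick: the
index-recovery and coverage experiment runs 60 replicates of the full
n = 424 design with B = 150 bootstrap draws each (median bias compared
against three Monte-Carlo standard errors; empirical 95% CI coverage
required to fall in [90%, 99%]); moment checks use $10^5$–$10^6$ draws.
Recovery of structural coefficients is asserted on a variant of the default
calibration with baseline means shifted upward, so that the deliberate
floor-censoring of the default generator (which mildly attenuates *b*)
does not masquerade as estimator bias.

## Known limitations

- Classification error from modal assignment is not propagated into the
  structural stage (no BCH/three-step correction).
- Boundary variance tests are conservative; the package flags rather than
  corrects them.
- The AR structure is defined on occasion lag by default, not month gaps.
- Only two moderator groups are supported for the index; the generator does
  not produce item-level scores, relapse outcomes, or MNAR mechanisms.
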