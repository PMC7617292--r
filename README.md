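# modmedgrowth

Who benefits from mindfulness-based cognitive therapy (MBCT) with
antidepressant-tapering support rather than maintenance antidepressants, and
through what mechanism? `modmedgrowth` implements the secondary analytic
chain used to answer that question in two-arm relapse-prevention trials for
recurrent depression, together with a calibrated synthetic-trial generator
so the whole chain is testable without patient-level data.

The chain has three stages:

1. **Latent profile analysis** over a mixed continuous/binary battery of
   baseline clinical-severity indicators (EM estimation with casewise
   handling of missing entries, BIC-based selection of the class count,
   relative entropy, z-scored profile summaries, distal comparisons).
2. **Latent growth curve models** for the six-occasion BDI-II series
   (months 0, 3, 9, 12, 18, 24): intercept-only, linear and quadratic
   shapes with homoscedastic, heteroscedastic or heteroscedastic
   lag-autocorrelated residuals, estimated by full-information maximum
   likelihood (FIML) under missingness at random.
3. **Latent-profile-moderated mediation.** Per profile *g*:

   ```
   M      = a0_g + a_g X + e_M                      (mediator: ΔFFMQ)
   η₁     = β10_g + b_g M + c'_g X + ζ              (latent linear slope)
   y_t    = η₀ + η₁ λ_t + η₂ λ_t² + ε_t             (BDI-II series)
   ```

   Conditional indirect effects `IE_g = a_g · b_g`, the **index of
   moderated mediation** `IE₂ − IE₁` (equal to `(a₂ − a₁)·b` under a shared
   b-path), the total effect `c`, per-equation R², covariate-adjusted
   sensitivity analysis, and percentile-bootstrap 95% CIs (case resampling
   stratified by arm). The FIML likelihood and its analytic gradient run in
   compiled code, so the bootstrap is fast enough for routine use.

## Worked example

```r
library(modmedgrowth)

cfg <- sim_config(seed = 2026)      # calibrated defaults, n = 424
dat <- simulate_trial(cfg)

ind <- dat[c(default_indicators()$name, "suicide_attempt")]
lpa <- fit_lpa(ind, K = 2, binary = "suicide_attempt", seed = 2026)
lpa
#> Latent profile model, K = 2
#>   n = 424  loglik = -19766.072  BIC = 39876.978
#>   weights: 0.527, 0.473
#>   relative entropy: 0.813

labels <- modal_assignment(lpa$posteriors)
spec <- medmod_spec(B = 1000, seed = 2026)
fit <- fit_medmod(dat, labels, spec, seed = 2026)
fit
#> Latent-profile-moderated mediation model (2 groups, n = 424)
#>   group 1: a = 6.490  b = -0.0270  indirect = -0.1755
#>   group 2: a = 15.726  b = -0.0270  indirect = -0.4253
#>   c' = 0.325  index of moderated mediation = -0.2498

boot <- bootstrap_medmod(dat, labels, spec, fit = fit)
boot$ci[boot$ci$term %in% c("ie_1", "ie_2", "index"), ]
#>     term estimate  lower  upper significant
#> 7   ie_1   -0.176 -0.259 -0.102        TRUE
#> 8   ie_2   -0.425 -0.505 -0.342        TRUE
#> 10 index   -0.250 -0.352 -0.137        TRUE

projected_change(fit$ie[[2]], 24)
#> -10.2
```

Reading the output: the trial arm raises mindfulness skills far more in the
higher-severity profile (a₂ ≈ 15.7 FFMQ points versus a₁ ≈ 6.5); each FFMQ
point gained lowers the symptom slope by about 0.027 BDI-II points/month
(b); the resulting conditional indirect effects are −0.18 and −0.43
points/month, and their difference (the index, −0.25, CI excluding zero)
evidences moderated mediation. Over the 24-month follow-up the mediated
pathway in the higher-severity profile projects to roughly a 10-point
BDI-II reduction.

`run_pipeline(pipeline_config(sim = sim_config(seed = 1), seed = 1))`
executes the whole chain (profiles → growth-model comparison → moderated
mediation with bootstrap → covariate-adjusted sensitivity rerun) and writes
CSV tables, a profile figure and a JSON manifest. A command-line front end
with `simulate` / `profiles` / `growth` / `mediate` / `pipeline`
subcommands is installed at `inst/cli/modmedgrowth.R`.

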