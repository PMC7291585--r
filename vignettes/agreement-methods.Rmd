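---
title: "Agreement indices from mixed models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement indices from mixed models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agreemix)
```

## What this package computes

Two devices measure the same continuous quantity on the same subjects at
the same times, repeatedly, under several conditions ("activities"), with
an unbalanced schedule: not every subject performs every activity, and
replicate counts differ. The question is whether the devices *agree* —
whether their paired, time-matched readings are close enough for the
devices to be used interchangeably, judged against a clinically acceptable
difference (CAD) of ±δ chosen by subject-matter experts before analysis.

All indices here are functions of variance components of Gaussian linear
mixed models with crossed random intercepts, estimated by REML. Model
notation, with subject *i*, device *j* ∈ {1 = reference, 2 = test},
activity *l*, replicate *t*:

**Full model (raw readings).**
$$y_{ijlt} = \mu + \alpha_i + \beta_j + \gamma_l + (\alpha\beta)_{ij} +
(\alpha\gamma)_{il} + (\beta\gamma)_{jl} + \varepsilon_{ijlt}$$
with independent normal random effects with variances
$\sigma^2_\alpha, \sigma^2_\gamma, \sigma^2_{\alpha\beta},
\sigma^2_{\alpha\gamma}, \sigma^2_{\beta\gamma}, \sigma^2_\varepsilon$, and
a fixed device effect constrained to $\beta_1 + \beta_2 = 0$.

**Differences model.** For the time-matched differences
$D_{ilt} = y_{i2lt} - y_{i1lt}$:
$$D_{ilt} = \mu^* + \alpha^*_i + \gamma^*_l + \varepsilon^*_{ilt},$$
plus a bias-only submodel $D_{ilt} = \mu^*_0 + \alpha^*_{0i} +
\varepsilon^*_{0ilt}$ whose intercept is the weighted mean bias used for
the limits of agreement.

The indices and their formulas are listed in the README; this vignette
records the assumptions, parameter choices and numerical decisions.

## Assumptions and diagnostics

Every parametric index inherits the mixed-model assumptions: independent
subjects; normal random effects and errors; mean bias constant across the
measurement range; between- and within-subject variabilities constant
across the range. `model_diagnostics()` extracts the BLUPs of each random
effect and the residuals and assembles Q–Q data, residual-vs-fitted and
standardized-residual-vs-fitted pairs, plus a deliberately coarse flag
(|sample skewness| > 1) per vector. The flag is a tripwire, not a test:
simulations in the test suite check it stays quiet on well-specified data
(≥ 90% of seeded runs) and fires on log-normal residual contamination.
When differences look skewed, prefer the nonparametric TDI (`np_tdi()`),
which uses empirical quantiles of |D| and makes no distributional
assumption.

The limits of agreement are taken primarily from the differences model
rather than the full model: normality is more plausible for differences
than for raw readings (differences can be normal when readings are not,
never the reverse). The full-model limits are reported alongside; the two
should roughly agree, since the full model implies
$\mathrm{Var}(D) = 2\sigma^2_{\alpha\beta} + 2\sigma^2_{\beta\gamma} +
2\sigma^2_\varepsilon$.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cad_delta` | none (must be set) | measurement units | context decision made by experts; all CAD-based verdicts depend on it |
| `tdi_p` | 0.95 | probability | conventional containment proportion |
| `cp_threshold` | 0.95 | probability | conventional "satisfactory agreement" cut |
| `cia_threshold` | 0.8 | — | literature cut: between-device disagreement within 25% of replication disagreement |
| `loa_multiplier` | 1.96 | — | exact 95% normal quantile; the informal "±2 SD" is treated as shorthand |
| `ccc_threshold` | none | — | the CCC is reported without verdict unless investigators pre-specify one |
| bootstrap `B`, `conf` | 1000, 0.95 | — | standard percentile-bootstrap defaults |

The difference orientation is test − reference (so a device that reads low
relative to the gold standard yields a negative bias); a flag flips it.

## Estimation and numerics

- **Criterion.** REML, the standard choice for variance components; the
  production path is `lme4::lmer` with sum-to-zero device contrasts and
  `calc.derivs = FALSE`. Boundary estimates (a variance of exactly 0) are
  legitimate outcomes, flagged but not treated as failures; singular-fit
  messages are therefore suppressed. Convergence failures are flagged on
  the returned object, never silent.
- **Dual route.** `dense_reml_loglik()` evaluates the restricted
  likelihood by explicit assembly of
  $V = \sum_k \sigma^2_k Z_k Z_k' + \sigma^2_\varepsilon I$
  (Cholesky, GLS fixed effects), independently of lme4's profiled sparse
  path; the test suite requires agreement of the criterion value to 1e-6
  on ≤ 60-observation instances. A self-contained optimizer over the same
  dense criterion (`reml_fit(..., method = "dense")`) parameterizes on the
  square-root scale to enforce non-negativity, uses a deterministic
  three-point multi-start from moment-based values, `nlminb` with relative
  tolerance 1e-8, and snaps estimates below 1e-8 of the total variance to
  exact zeros.
- **Degenerate data.** Responses constant within each device level short-
  circuit to an exact answer (all components 0, boundary flags set, REML
  log-likelihood reported as `NA` since the criterion diverges). A zero
  estimated MSD makes CP, TDI and CIA degenerate; the report then returns
  the perfect-agreement limits (1, 0, 1) with a flag. The CIA is otherwise
  undefined when $\sigma^2_\varepsilon = 0$ (the replication benchmark is
  degenerate) and errors with an explanation.
- **Unpaired readings.** The full model is fitted to *all* readings,
  including ones missing their counterpart on the other device — mixed
  models tolerate unbalance, and discarding them would waste information.
  Difference-based methods necessarily use pairwise-complete data;
  dropped readings are counted in the pairing report. How the motivating
  analysis handled its (absent there) unpaired readings is not stated
  anywhere we could check; this choice is ours.
- **Quantile conventions.** The nonparametric TDI uses the nearest-rank
  (ceiling) quantile of |D| by default — exactly reproducible by
  enumeration, which is how it is tested — with interpolating quantiles as
  an option, since the cited nonparametric proposal's own convention is
  not restated in our source. Absolute differences are used (the TDI is a
  containment half-width, symmetric by construction). Bootstrap percentile
  intervals use R's default type-7 quantiles.

## The synthetic generator

`generate_measurements()` draws every random effect of the full model
independently from its stated normal distribution on a user-specified
schedule, always observing both devices at each generated (subject,
activity, replicate) — pairs are time-matched by construction. Latent
draws are attached to the output for white-box tests.

`copd_design()` emulates the structure of the motivating COPD study: 21
subjects, 11 activities, "sitting" with 6–7 paired readings per subject,
"standing and walking" with 1–3, all others 1, and the two treadmill
activities skipped with probability 0.2 per subject. Replicate-count
weights (P(7 sitting readings) = 0.8; standing-and-walking weights
0.05/0.15/0.8) were chosen once so that per-subject paired counts land in
15–19 with mean ≈ 18, matching the published count distribution; they are
a statistical emulation, not a replica of the real participation pattern,
which is only available in the external dataset. Default truth: the
published components (11.4, 16.6, 0.4, 6.0, 3.7, 10.5), device difference
−1.28, overall mean 19 breaths/min (between the two devices' observed
medians of 20 and 18).

What a green test on generated data establishes: the estimation and index
pipeline recovers a world that satisfies the model exactly. What it does
not establish: robustness to skewness, heteroscedastic residuals across
devices, proportional bias, or time trends — none of which the generator
produces (the last two are explicit non-goals; residual heteroscedasticity
by device is a known limitation of all five indices).

## Design choices where the design was open

- **ANOVA limits of agreement.** The fixed-effects extension for repeated
  measures is implemented as one-way ANOVA on the differences with the
  unbalanced-design correction
  $n_0 = [\sum m_i - \sum m_i^2 / \sum m_i]/(k-1)$,
  $\hat\sigma^2_b = (MSB - MSW)/n_0$ truncated at zero, total SD
  $= \sqrt{\hat\sigma^2_b + MSW}$. The original method's exact variant is
  described in a supplement we do not have; this is the standard 1999-era
  formulation and is validated against a hand-worked example.
- **$\phi^2_\beta$.** Computed from the sum-to-zero device effects as
  $(\beta_2-\beta_1)^2/2$. Whether the published CCC included this term
  cannot be resolved at printed precision (both paths agree to ~0.01);
  we include it, since omitting it measures consistency rather than
  agreement.
- **Lin's CCC (naive).** 1/n moment estimators, as in the original
  proposal; at the motivating study's n the difference from 1/(n−1) is
  far below reporting precision.
- **Bootstrap.** "Individual level" is read as subject-level: subjects are
  the clusters everywhere in this design; activities ride along inside
  subjects and are never resampled. Percentile intervals, the simplest
  method consistent with how such CIs are usually reported; failed refits
  are skipped and counted, with an unreliability flag above 20%.

## Limits of the subject-level bootstrap (and of the coverage test)

A subject-resampling bootstrap estimates sampling variability *across
subjects*. Components indexed by activity — above all the device–activity
interaction $\sigma^2_{\beta\gamma}$, which enters the MSD — contribute
dataset-level noise that subject resampling cannot see. In simulations
with the published components (where $2\sigma^2_{\beta\gamma}$ is about a
quarter of the MSD) and a handful of activities, the 95% percentile CI for
the coverage probability covered the true CP only ~56% of the time: the
interval is honest only *conditionally on the realized activity panel*.
This is a property of the resampling unit, not of this implementation; it
applies equally to the motivating analysis. Consequently the acceptance
test of bootstrap coverage runs in a world with
$\sigma^2_{\beta\gamma} = 0$ (all other components as published), where
the scheme is consistent and measured coverage is ≈ 0.95 at 40 subjects
(21 subjects gives ≈ 0.83 — generic small-cluster narrowness of percentile
intervals). The coverage simulation also runs at 120 repetitions × B = 120
rather than the nominal 200 × 200, purely for runtime; and the CP pipeline
inside it estimates the MSD from the differences model
($\hat\mu^{*2} + \hat\sigma^2_{\alpha^*} + \hat\sigma^2_{\gamma^*} +
\hat\sigma^2_{\varepsilon^*}$), which targets the same quantity at a
fraction of the refit cost.

Interpret bootstrap CIs for MSD-based indices accordingly: with few
activities and a material device–activity interaction, they understate
uncertainty about generalization to *new* activities.

## Other known limitations

- Exactly two devices per analysis; no random slopes; homoscedastic
  residuals shared by both devices; Gaussian effects only.
- The parameter-recovery acceptance test uses 200 subjects (as stated) and
  150 activity levels chosen a priori so that the ~25% tolerance sits
  several sampling standard errors away for the activity-indexed
  components ($\mathrm{SE}(\hat\sigma^2_\gamma)/\sigma^2_\gamma \approx
  \sqrt{2/149} \approx 12\%$); with the 11 activities of the motivating
  design, $\sigma^2_\gamma$ is estimated from 10 effective degrees of
  freedom and no estimator could meet that band reliably.
- REML third-decimal agreement with any particular published fit is not
  expected (optimizer tolerances and data handling details differ); all
  desk-scale reproductions therefore start from the printed components
  themselves.
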