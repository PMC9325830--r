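---
title: "Dose-driven dermal absorption estimation: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-driven dermal absorption estimation: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermabs)
```

## The problem

Dermal absorption values translate external dermal exposure into potential
systemic exposure in non-dietary risk assessment of pesticides. In vitro
penetration studies (diffusion cells with human or rat skin, OECD TG 428
style) report, per tested dose group, the percentage of the applied dose
recovered in the receptor fluid and in the skin. European practice treats
this *relative* absorption value as a property of the tested concentration,
and extrapolates it *pro rata* — inversely with concentration — when an
in-use dilution falls outside the tested range. That convention disconnects
the absorption estimate from the exposure dose: the quantity that, by the
basic toxicological axiom, actually drives risk.

`dermabs` implements the competing, dose-driven view. Across dose groups the
*absolute* absorbed dose $A$ (µg/cm²) is modelled against the *absolute*
applied dose $D$ (µg/cm²) on the decadic log scale,

$$\log_{10} A = \beta_1 \log_{10} D + \beta_0,$$

and the fitted slope $\beta_1$ is read as evidence about how absorption
scales with dose.

## The slope as a hypothesis test

Four slope regimes carry distinct regulatory meanings:

* $\beta_1 = 1$ — absolute absorption is directly dose-proportional; the
  relative absorption value is one constant for the product, independent of
  dose, and the back-transformed intercept is that constant.
* $\beta_1 = 0$ — the absolute absorbed amount ignores the applied dose.
  This is the premise of the pro-rata extrapolation: relative absorption
  then rises inversely with dose without bound, which is biologically
  implausible.
* $0 < \beta_1 < 1$ — relative absorption rises as dose falls, but less
  than pro-rata.
* $\beta_1 > 1$ — relative absorption falls as dose falls; smaller doses
  yield disproportionately less systemic exposure.

`classify_slope()` turns an 80% confidence interval of the slope into
exactly one of the categories `ZERO`, `BETWEEN_0_1`, `ONE`, `ABOVE_1` or
`UNCERTAIN`, so that the four hypotheses are each assessed with 95%
confidence. The partition applies rules in a fixed order: an interval
entirely below zero is `UNCERTAIN` (an inverse dose-absorption relation is
implausible — in practice an artefact of stratum corneum residue); an
interval spanning both 0 and 1 is `UNCERTAIN` (too wide to conclude); then
containment of 1, containment of 0, entirely above 1, and entirely inside
(0, 1) are checked in turn. Intervals are **closed**: a CI that exactly
touches 0 or 1 counts as containing it. That tie-break is our choice — the
verbal scheme does not specify boundary behaviour — and it is the
conservative one, producing more "compatible" verdicts. A negative interval
maps to `UNCERTAIN` rather than a sixth category, and intervals sitting just
above 1 (lower bound in (1, 1.1]) carry a proximity note instead of a
separate class, since such slopes are rarely distinguishable from 1 in
practice.

`interpret_slope()` returns the interpretation ledger per regime (absolute
and relative penetration, small-dose extrapolation limit, ADME reading,
predicted internal exposure, plausibility). One ambiguity was resolved
deliberately: the "constant and independent of dose (pro-rata)" reading of
absolute penetration belongs to the slope-0 regime — a slope of 0 means the
applied dose has no effect on the absolute amount absorbed, which is exactly
the pro-rata premise — while slope 1 reads as *directly dose-proportional*
absolute penetration with *constant relative* absorption.

## The average absorption value

When a slope of 1 is assumed (or supported), fitting is unnecessary. The
least-squares intercept under a fixed unit slope is

$$\hat\beta_0 = \operatorname{mean}\left(\log_{10} A_i - \log_{10} D_i\right),$$

and the average dermal absorption value is its back-transformation

$$\mathrm{DA}_{\mathrm{ave}}\,[\%] = 10^{\hat\beta_0} \times 100,$$

which is algebraically the geometric mean of the per-group relative
absorption percentages (`da_ave()`; the identity is property-tested). The
free-slope analogue is $\mathrm{DA}_{\mathrm{rel|model}} = 10^{\hat\beta_0}
\times 100$ from the unconstrained fit (`da_rel_model()`). A displayed
formula in some reports reads "$10^{\log_{10}(\text{intercept})}$", which is
self-inconsistent; published example tables are consistent with
$10^{\text{intercept}} \times 100$, which is what we implement, and both
the rounded-intercept and full-precision paths are exposed (pass a bare
rounded intercept, or a fitted model object).

`worked_table()` reproduces the full hand calculation per product —
per-group logs, differences, mean difference, DA~ave~, predicted absorbed
doses and column sums. All arithmetic is carried at full floating
precision; rounding to two decimals happens only at rendering. For a fitted
slope below 1 the DA~ave~-predicted total absorbed dose exceeds the
observed total (a conservative direction for risk assessment); above 1 it
falls short, which is why `da_ave()` warns "case-by-case" when its
companion free-slope fit exceeds 1.

Concentrates and in-use dilutions have very different physico-chemical
properties; the table-level API (`da_ave_table()`) refuses to pool them and
requires a preparation filter when a table contains both.

## Model machinery and conventions

* **Fitting.** `fit_loglog()` is ordinary least squares of $\log_{10} y$ on
  $\log_{10} x$ via `stats::lm()`. Records non-positive on either axis are
  excluded with a warning (dose-group means are strictly positive in clean
  data); an optional limit-of-quantification floor exists but is off by
  default because silent substitution biases slopes. Decadic logs are used
  everywhere user-facing; natural logs appear only inside likelihoods.
* **Confidence intervals** are two-sided Wald $t$-intervals with $n-2$
  degrees of freedom — the default of the R modelling stack this field
  uses. `compatible_with()` is closed-interval containment.
* **AIC** follows the full Gaussian maximum-likelihood convention,
  $n\ln(2\pi\,\mathrm{RSS}/n) + n + 2k$ with $k = 3$ (slope, intercept,
  residual variance), matching `stats::AIC()` on the equivalent `lm`. A
  numerically zero RSS returns $-\infty$ as a documented sentinel.
* **Model-form comparison.** `compare_model_forms()` fits
  `absolute_vs_dose` and `relative_vs_concentration` on the same records.
  The two forms have different response variables; their AICs are compared
  naively (no Jacobian adjustment for the response transformation), and the
  result carries a `different_response` flag. Note that because
  $\mathrm{DA}\% = 100\,A/D$, the concentration form is an exact
  reparameterisation of the dose form whenever dose is proportional to
  concentration — the comparison only discriminates when applied volumes
  (and hence doses) decouple from concentration across records, as in
  heterogeneous database collections.
* **Mixed models.** `fit_mixed()` fits a random-intercept-by-product model
  with `lme4::lmer()` — random intercept only: with 3–4 doses per product a
  random slope would be unidentifiable. Variance components are REML; the
  reported AIC is from the ML refit so fixed-effect structures stay
  comparable; both are labelled. Marginal and conditional $R^2$ use the
  variance decomposition $R^2_m = \sigma^2_f/(\sigma^2_f + \sigma^2_u +
  \sigma^2_e)$ and $R^2_c = (\sigma^2_f + \sigma^2_u)/(\sigma^2_f +
  \sigma^2_u + \sigma^2_e)$, with $\sigma^2_f$ the variance of the
  fixed-effect predictions.
* **Isoslope plot.** `isoslope_plot()` draws the log–log scatter with the
  identity line (100% absorption) and dotted unit-slope isoslopes at
  tenfold spacings (10, 1, 0.1%); a fitted line parallel to the isoslopes
  means constant relative absorption, and its height is the average value.

## The penetration-probability toy model

Two extreme cases bracket how relative absorption can depend on dose when
each molecule penetrates independently with some probability. If only the
molecule nearest the barrier penetrates ($p = 1$, all others 0), the
expected relative absorption is $100/N$ percent — at doses of 1, 2, 10 and
100 molecules: 100, 50, 10 and 1% (absolute absorption constant, slope 0).
If every molecule shares $p = 0.1$, relative absorption is 10% at any dose
(slope 1). `expected_relative_absorption()` computes the expectation;
`simulate_penetration()` draws a seeded Bernoulli realisation. Probability
gradients over molecules are representable as arbitrary probability
vectors; no spatial or diffusion model is attempted.

## The synthetic study generator

Real regulatory databases of dermal absorption studies are proprietary, so
method validation runs on synthetic tables with the same statistical
structure (`generate_study()`, `generate_database()`): products tested at
$\ge 3$ in-use dilution concentrations; applied dose coupled to
concentration through a fixed application volume ($D = V \cdot c$, with 10
µL/cm² the conventional default, so 1 g/L at 10 µL/cm² gives 10 µg/cm²);
lognormal residual noise and a lognormal product-level random intercept:

$$\log_{10} A = \beta_0 + u_p + \beta_1 \log_{10} D + \varepsilon,\quad
u_p \sim N(0, \tau^2),\ \varepsilon \sim N(0, \sigma^2).$$

Defaults, chosen once as field-realistic and not tuned thereafter: four
concentrations log-spaced over two orders of magnitude (mirroring the
severalfold-to-60-fold applied-dose ranges of multi-concentration study
programmes), $\beta_0 = -1.65$ (≈ 2.2% receptor-fluid absorption, a typical
dilution average), $\sigma = 0.2$ and $\tau = 0.3$ on the log10 scale — no
variance figures for real study noise are published, so these are our
choice, documented here. Recoveries are kept in (0, 100] by rejection
resampling rather than truncation, to preserve log-scale Gaussianity; the
resample count is reported. Optional per-group volume jitter (uniform) or
lognormal volume spread decouple dose from concentration, emulating
heterogeneous collections rather than a single harmonised protocol.

What the generator deliberately does **not** emulate: co-formulant
chemistry, solubility-driven slope deviations of solid formulations,
wash-in/wash-off effects, inter-laboratory differences. Passing tests on
synthetic data therefore demonstrate the statistical machinery — estimator
identities, interval coverage, parameter recovery — not the biological
adequacy of the slope-1 assumption for any real product.

## Problem sizes and verification

The test suite validates (problem sizes stated here are the package's own
choices): OLS against an independent closed-form normal-equations oracle on
random instances; the AIC against an independently coded Gaussian
log-likelihood; 95% CI coverage of a true unit slope at 95% ± 3 points over
2000 simulated four-dose studies ($\sigma = 0.2$); mixed-model slope
recovery (median $|\hat\beta_1 - 1| \le 0.05$) and variance-component
recovery (median relative error ≤ 25%) over 200 replicates of 20 products
× 4 concentrations; and the AIC direction of the model-form comparison over
200 database-like tables of 40 records generated at slope 0.89 with
heterogeneous volumes (log10 SD 1) — at a true slope of exactly 1 the two
forms are reparameterisations with equal expected RSS, so the direction is
only testable away from 1; the published database slope estimate for
dilutions, 0.89, is used. The three bundled worked-example studies
reproduce every hand-calculation cell to ±0.01 at two decimals.

## Known limitations

* Dose-group means only; replicate-level (per-donor) variability and
  mass-balance QC are out of scope.
* The slope classification operates on one study's interval at a time; no
  multiplicity adjustment across a database of studies is applied.
* Flux / maximum-flux (Fick's law) absorption metrics are not implemented —
  the package's scope is the cumulative-recovery framework used in current
  regulatory practice.
* The in vivo "systemic dose" definition (excreta, carcass, blood) is left
  to the data supplier; the schema stores it in `rf_pct` with
  `test_system = "in_vivo_rat"`.
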