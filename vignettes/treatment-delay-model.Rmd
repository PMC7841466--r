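---
title: "Modeling tumor control and metastasis risk under treatment delay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tumor control and metastasis risk under treatment delay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaytcp)
```

## The question

When treatment for a diagnosed solid tumor is postponed — by resource
shortages, triage policy, or patient choice — two things get worse: the
primary tumor accumulates clonogenic cells, lowering the probability that
treatment will control it locally, and the growing tumor has more time and
more cells with which to seed distant metastases. `delaytcp` quantifies
both effects as functions of the delay, for cancer types whose growth
kinetics and upstaging behavior have been measured.

This is deliberately a minimal-parameter model built for delays of a few
months, i.e. a few doubling times. It is a decision-analytic tool for
ranking risks and delays, not a forecasting model for individual patients.

## Model structure and assumptions

Three assumptions define the single-patient model:

1. **Exponential primary growth.** The primary cell count is
   $P(t) = P_0 e^{gt}$ with $P_0$ the burden at diagnosis and $g$ a
   patient-specific growth rate (per month). Over a few doubling times
   exponential growth is an adequate approximation; saturating forms
   (Gompertz, power-law) matter on multi-year horizons and are out of
   scope.
2. **Metastasis hazard proportional to burden.** New metastases arise as a
   nonhomogeneous Poisson process with hazard
   $M(t) = M_0 + k \int_0^t P(u)\,du = M_0 + \frac{k P_0}{g}(e^{gt} - 1)$.
   The probability of at least one new metastasis by delay $t$ is
   $PM(t) = 1 - e^{-\Lambda(t)}$ with
   $\Lambda(t) = M_0 t + \frac{k P_0}{g}\!\left(\frac{e^{gt}-1}{g} - t\right)$.
   We take $M_0 = 0$: patients have no metastases at primary diagnosis.
3. **Poisson tumor control.** Treatment leaves each cell alive with
   probability $S$; the number of surviving clonogens is Poisson with mean
   $S\,P(t)$, so local control (zero survivors) has probability
   $\mathrm{TCP}(t) = \exp(-S P_0 e^{gt})$.

Population heterogeneity enters through the growth rate:
$g \sim \mathcal{N}(G, \sigma^2)$, untruncated. The left tail deliberately
includes dormant ($g = 0$) and spontaneously regressing ($g < 0$) tumors;
for slow-growing cancers with $\sigma$ comparable to $G$ this mass is
non-negligible and is what pulls the favorable bound of the TCP-loss band
down to zero.

## Parameters and calibration

The five adjustable parameters per cancer, and where they come from:

| Parameter | Units | Source |
|---|---|---|
| $P_0$ | cells | sphere of the stage-typical diameter at $10^8$ cells/cm³ |
| $S$ | — | solve $\exp(-S P_0) = 0.9$: 90% baseline control without delay |
| $G$ | month⁻¹ | $\ln 2 /$ (median doubling time), days at 30 per month |
| $\sigma$ | month⁻¹ | doubling-time spread, see below |
| $k$ | month⁻¹cell⁻¹ | observed upstaging fraction at a stated delay |

The 30-day month is a fixed convention; it is what makes
$G = \ln 2/(99/30) = 0.210$ month⁻¹ for a 99-day doubling time.

**Spread to $\sigma$.** Doubling-time spreads are published either as full
ranges or as interquartile ranges. Each bound is treated as a symmetric
quantile of the growth-rate normal: converting the bounds to growth rates
(the *shorter* doubling time gives the *faster* rate, so the bounds swap),
each one-sided offset from $G$ is divided by $z = 2$ (full range read as
mean ± 2σ) or $z = 0.674$ (quartile offset), and $\sigma$ is the geometric
mean of the two one-sided estimates. The geometric mean accommodates the
asymmetry that the days→rate inversion induces.

**Calibrating $k$.** Given an observed fraction $p$ of patients upstaged
with new metastases after a delay $t_{obs}$, the default `"point"` mode
solves $PM(t_{obs}) = p$ at $g = G$ in closed form:
$k = -\ln(1-p)\, g^2 / \left(P_0 (e^{g t_{obs}} - 1 - g t_{obs})\right)$.
The alternative `"distributional"` mode root-solves so the
growth-rate-*averaged* $PM$ equals $p$. Because $PM$ is convex in $g$,
averaging raises the mixture probability and the distributional $k$ is
always below the point $k$ (about 0.7% lower for head and neck, 2% for
lung). The point mode is the default for determinism and because it matches
the published constants most closely; the mode used is recorded in the
parameter metadata.

**Bundled parameter sets.** Three cancers are bundled with their literature
inputs: head and neck (3.0 cm, doubling 99 days, range 61–112; 60% upstaged
at 14.9 months), colorectal (5.0 cm, 211 days, range 112–404; 17% at 5
months), and non-small cell lung (0.5 cm, 348 days, IQR 222–492; 8% at 12
months). `published_parameters()` exposes two precision modes. `"derived"`
runs the whole chain at full precision. `"printed"` (the default) runs the
chain at full precision but substitutes the published rounded value of $k$;
this mode reproduces the published risk table to two decimals, because that
table was evidently computed from a mix of rounded and unrounded
intermediates. Recomputing $k$ from scratch lands within ±2% of the
published constants (point mode); the exact rounding chain behind the
published values is not recoverable, so agreement at the percent level is
the honest statement.

## Distributional estimates

```{r table}
sets <- lapply(cancer_labels(), published_parameters)
format_risk_table(delay_risk_table(sets, delays = c(2, 6)))
```

- **Means** are Gauss–Hermite quadrature expectations over the growth-rate
  normal, 128 nodes by default (cached; 64 vs 256 nodes agree to well below
  1e-8 relative for these integrands, which are smooth and effectively
  bounded).
- **Bands** are plug-in percentile intervals: TCP and PM are monotone in
  $g$, so their 2.5th/97.5th percentiles are the model evaluated at
  $g = G \mp 1.959964\,\sigma$ (orientation follows the sign of the
  monotonicity — TCP decreases in $g$, PM increases). The published
  intervals carry both "95% CI" and percentile labels; the percentile
  semantics is what reproduces them.
- **TCP loss** is reported in percentage points against the baseline
  $\mathrm{TCP}(0) = \exp(-S P_0)$ (exactly 0.9 for the bundled sets), not
  against $E[\mathrm{TCP}(0)]$ — identical here, since TCP at zero delay
  does not depend on $g$.
- **Display convention:** two decimals, and negative TCP-loss lower bounds
  floored at 0.00 — a 97.5th-percentile TCP above baseline (possible for
  lung, where regression mass is substantial) means the favorable outcome
  is "no loss", not a negative loss. Full precision is always available
  from `delay_risk_table()` directly.

## Numerical choices

- The closed forms are evaluated through `expm1`-style primitives
  $(e^x-1)/x$ and $(e^x-1-x)/x^2$ with series branches below
  $|gt| < 10^{-8}$, because the mixture integrates across $g = 0$ and the
  naive forms lose all precision there. Continuity at $g = 0$ is tested to
  1e-6 relative at $g = \pm 10^{-12}$.
- Probabilities are computed in double precision with no clamping;
  `-expm1(-Λ)` keeps $PM$ exact for tiny hazards.
- Degenerate mixtures ($\sigma = 0$) short-circuit to the point model, and
  all interval estimates collapse to the mean.
- The distributional $k$ root-solve brackets two decades around the
  closed-form point solution with a tolerance scaled to that solution
  (absolute tolerances are meaningless at $k \sim 10^{-12}$).

## The cohort simulator

`simulate_cohort()` is an independent stochastic implementation of the same
semantics, used to cross-validate the quadrature: each patient draws
$g \sim \mathcal{N}(G, \sigma^2)$, a control Bernoulli with the
Poisson-zero probability (optionally, sampling the surviving-clonogen
Poisson count directly — identical in distribution), and a metastasis
Bernoulli from $1 - e^{-\Lambda}$. `simulate_event_times()` additionally
realizes the full event process by thinning against the end-of-horizon
hazard, which majorizes because the hazard is nondecreasing in time for
every sign of $g$. All draws come from one seed in fixed vectorized
positions, so results are bitwise reproducible and independent of
evaluation order.

The test suite requires the simulated control and metastasis fractions to
sit within three binomial standard errors of the quadrature expectations at
every bundled (cancer, delay) cell — at $n = 10^6$ in the end-to-end check,
$n = 10^5$ in unit tests — and the empirical first-event distribution to
match $PM$ to Kolmogorov distance 0.015 at $2 \times 10^4$ draws. These
sizes keep the default suite under a minute while leaving Monte Carlo error
well below the differences that would indicate a real defect.

## What the synthetic cohorts do and do not show

The simulator emulates exactly the model's assumptions — exponential
growth, proportional hazard, normal growth-rate mixture, independent
patients. Agreement between simulator and quadrature therefore validates
the *implementation* (closed forms, quadrature, percentile orientation),
not the *model*: it says nothing about saturating growth, surface-area
metastasis emission, inter-lesion seeding, microenvironment effects, or
treatment countermeasures during real-world delays, none of which are
modeled. Passing tests mean the arithmetic is right and the published
numbers are reproduced, not that a real patient's risk follows these
curves.

## Known limitations

- Exponential growth overestimates burden for delays long enough for
  saturation to matter (years); the model is intended for month-scale
  delays.
- The untruncated normal growth-rate mixture puts mass on biologically
  extreme regression rates for wide-σ cancers; it is retained because the
  percentile bands of the published analysis depend on it.
- $k$ is calibrated from a single (probability, time) observation per
  cancer; its uncertainty is not propagated.
- $P_0$, cell density, and the 90% baseline TCP are treated as known
  constants; uncertainty in them is out of scope.
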