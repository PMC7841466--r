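# delaytcp

Quantitative risk estimates for delaying cancer treatment. `delaytcp`
implements a decision-analytical model of how a treatment delay of `t`
months changes two outcomes for a solid tumor diagnosed today:

- **local tumor control probability (TCP)** — the chance that treatment
  eradicates every clonogenic tumor cell, and
- **the probability of new metastases** arising during the delay.

It is aimed at radiation oncologists, modelers, and health-policy analysts
who need order-of-magnitude answers to "how much does waiting two months
cost this patient?" for tumors with published growth kinetics.

## The model

The primary tumor grows exponentially from its burden at diagnosis,
`P(t) = P0 e^{g t}`, and sheds metastases as a nonhomogeneous Poisson
process whose hazard is proportional to the current cell count,
`M(t) = M0 + (k P0 / g)(e^{g t} - 1)`. The probability of at least one new
metastasis by delay `t` is

    PM(t) = 1 - exp(-Λ(t)),   Λ(t) = M0 t + (k P0 / g)((e^{g t} - 1)/g - t)

and local control after treatment at delay `t` follows the Poisson
clonogen-survival model with surviving fraction `S`:

    TCP(t) = exp(-S · P0 · e^{g t})

Patient heterogeneity enters through a normally distributed growth rate
`g ~ N(G, σ²)` — including dormant (`g = 0`) and regressing (`g < 0`)
tumors — integrated by Gauss–Hermite quadrature to give means and
2.5th/97.5th percentile bands of TCP loss and metastasis risk.

All five parameters are calibrated from literature-style inputs:
`P0` from spherical geometry at 10⁸ cells/cm³, `S` from a 90% baseline TCP,
`G` and `σ` from doubling-time summaries (30-day months), and `k` from an
observed upstaging fraction at a stated delay. Calibrated sets for head and
neck (fast-growing), colorectal (intermediate), and non-small cell lung
(slow-growing) cancer are bundled.

## Worked example

```r
library(delaytcp)

hn <- published_parameters("head_and_neck")
hn
#> Tumor parameter set: head_and_neck
#>   P0 (cells)        1.41e+09
#>   S  (surv. frac.)  7.45e-11
#>   G  (per month)    0.21
#>   sigma (per month) 0.0282
#>   k  (/month/cell)  1.51e-12
#>   M0 (per month)    0

format_risk_table(delay_risk_table(list(hn), delays = c(2, 6)))
#>          cancer delay_months tcp_loss_mean tcp_loss_lo tcp_loss_hi
#> 1 head_and_neck            2          4.84        3.37        6.40
#> 2 head_and_neck            6         21.26       13.40       30.42
#>   met_risk_mean met_risk_lo met_risk_hi
#> 1          0.49        0.47        0.51
#> 2          5.96        5.23        6.80
```

Reading: a two-month delay costs this head-and-neck patient population a
mean 4.84 percentage points of local control (95% of patients between 3.37
and 6.40) and adds a 0.49-point risk of new metastases; at six months the
mean loss grows to 21.26 points and the metastasis risk to 5.96 points.

A seedable Monte Carlo cohort simulator provides an independent stochastic
check of the analytic results:

```r
simulate_cohort(hn, t = 2, n = 1e5, seed = 1)
#> Cohort of 100000 at t = 2 months (seed 1):
#>   local control    0.8515 (SE 0.0011)
#>   new metastasis   0.0048 (SE 0.00022)
```

both within sampling error of the quadrature values (mean TCP 85.2%, mean
metastasis probability 0.49%).

A command-line interface wraps the same functions
(`inst/cli/delaytcp <calibrate|table|curves|simulate>`), emitting CSV or
JSON; `curves` produces the dense 0–12 month mean/percentile series behind
the delay-response figures.

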