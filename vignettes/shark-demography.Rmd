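---
title: "Demographic analysis of an exploited coastal shark: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic analysis of an exploited coastal shark: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elasmodem)
```

elasmodem implements the standard stochastic demographic workflow used to
assess data-poor elasmobranch stocks, parameterised out of the box for the
smalltail shark (*Carcharhinus porosus*) of the Brazilian northern coast.
This vignette explains the model, the numerical choices, and — importantly —
what the synthetic-data-driven tests do and do not establish.

## The model

The analysis rests on a female-only, age-structured Leslie matrix. Annual
survival at age $x$ is $s_x = e^{-(M_x + F_x)}$, where $M_x$ is natural and
$F_x$ fishing mortality (both instantaneous, 1/yr); fecundity $m_x$ is a
constant $\bar m$ female pups per female per year from the integer maturity
age onward (a biennial litter cycle is averaged into $\bar m$). Under the
default **pre-breeding census** the matrix has age classes $1..t_{max}$ and
its fertility row carries first-year survival inside the fertility element,
$f_x = s_0\, m_x$ ("reproduction first, then survival"). The dominant
eigenvalue gives $\lambda$; $r = \ln\lambda$; $R_0 = \sum_x l_x m_x$; the
generation time $T$ is the mean age of mothers at the stable age
distribution, $\sum x \lambda^{-x} l_x m_x / \sum \lambda^{-x} l_x m_x$
(the alternative $\ln R_0 / r$ is reported as `T_R0` but is not the
default).

A design note on the census convention: descriptions of this workflow
sometimes write the fertility element as $s_x m_{x+1}$ while still calling
the census pre-breeding. The two readings cannot both hold: on classes
$1..t_{max}$, $f_x = s_x m_{x+1}$ violates the Euler–Lotka identity
$\sum_x \lambda^{-x} l_x m_x = 1$ by a factor $\lambda/s_0$. We therefore
use $f_x = s_0 m_x$ for the pre-breeding census and provide
`census = "post"` (classes $0..t_{max}$, $f_x = s_x m_{x+1}$), both of
which satisfy Euler–Lotka exactly; for this stock the two agree in
$\lambda$ to machine precision. The choice is validated by reproduction of
the published elasticity decomposition to three decimals in two scenarios
(`test-leslie.R`).

Elasticities $e_{ij} = a_{ij} v_i w_j / \lambda$ always sum to one and are
grouped as fertility ($e_1$), juvenile survival ($e_2$, transitions from
ages below the maturity age) and adult survival ($e_3$). In the Monte
Carlo, the grouping boundary is held at the central maturity age even when
a draw's own maturity age differs, so the split is comparable across
draws; the draw's matrix itself always uses the drawn maturity age.

## Mortality estimation

Eleven empirical natural-mortality estimators are provided (Pauly; Jensen
1–3; Rikhter & Efanov; Hoenig teleost and cetacean; Hewitt & Hoenig;
Mollet & Cailliet; Peterson & Wroblewski; Chen & Watanabe). Numerical
choices that matter:

* **Rikhter & Efanov** is implemented as $1.521/t_{mat}^{0.72} - 0.155$
  (subtraction); this is the only reading that reproduces the published
  value (0.250) at $t_{mat} = 6.28$. Non-positive results are flagged
  invalid rather than returned.
* **Peterson & Wroblewski** takes weight in the regression's native grams;
  the user-facing length–weight relation remains in kg/cm and is converted
  internally. The bundled profile ships a *synthetic* length–weight
  stand-in ($W = 5\times10^{-6} L^3$ kg) documented as such: no weight data
  exist for this stock, and the stand-in exists solely so the estimator can
  occupy its 1/11 slot in the uncertainty support.
* **Chen & Watanabe** switches from the juvenile to the senescent branch at
  the first integer age above $t_{mat}$; at exactly $t = t_{max}$ the
  senescent formula is 0/0 and its analytic limit
  $k e^{k t_{max}} / (e^{k t_{max}} - e^{k t_0})$ is used so schedules
  cover the whole age grid.
* Two longevities coexist deliberately: `t_max_mortality` (14 yr, the
  oldest age in the catch) feeds the longevity-based estimators — only that
  value reproduces the published Hoenig-family numbers — while `t_max`
  (12 yr, the growth study's maximum) bounds the projection matrix.
* `aggregate_M()` averages methods arithmetically; age-dependent methods
  contribute their age-mean by default (midpoint and exclusion are
  options). With computed schedules this yields ≈0.24, not the published
  0.261; the published average is not exactly recoverable because the
  age-dependent schedules behind it were never printed, and we document
  the mismatch rather than tune it away.

Total mortality comes from catch curves (OLS on log numbers-at-age over
the descending limb, default [modal age, last age with ≥2 fish]) and from
Beverton & Holt mean-age and mean-length estimators in their standard
forms; the fitting range and the recruitment parameters default from the
composition itself (modal age; length at the modal age) and are
overridable. Mean age uses class midpoints to reduce the discretisation
bias of floor-binning.

## Uncertainty propagation

Each Monte Carlo draw independently samples: one of the eleven M members
(p = 1/11; age-dependent members are *recomputed* for the draw's maturity
and maximum age), one of the four fixed Z estimates (p = 1/4), maturity
age over {5, 6, 7} and maximum age over {11, 12, 13} with probabilities
{0.25, 0.5, 0.25}, and fecundity from Normal(1.48, 0.57) truncated at zero
by redraw (flooring at zero is available but changes the mean). Fishing
mortality per age is $F_x = \max(Z - M_x, 0)$ from the scenario's
recruitment age (2 yr for the realistic scenario, 6 yr for the
adults-only scenario). Scenarios run on *shared* draws, so per-draw
comparisons (e.g. the ordering $\lambda_1 \ge \lambda_3 \ge \lambda_2$)
are paired and exact. Seeded runs are bit-reproducible. Confidence
intervals are percentile-based (2.5/97.5%); the CI method behind the
published intervals is unstated.

Decline projections use $N_t = e^{rt}$, reported both at the mean $r$ and
mean $T$ (the convention behind published decline tables) and per draw
with intervals. The IUCN criterion-E check compares the three-generation
decline with 50% *inclusively*, and its output carries the caveat that a
projected decline is a proxy for — and overstates — a true extinction
probability, since no density dependence or demographic stochasticity is
modelled.

## Rebound and extinction metrics

The rebound potential solves the replacement total mortality $Z_{sus}$
(bisection on $\lambda(Z) = 1$ to $|\lambda - 1| < 10^{-8}$; the constant
Z replaces mortality at *every* age, including the first-year survival
inside fertility) and sets $r_Z = 2(Z_{sus} - M)$, the logistic
surplus-production rate implied by fishing at MSY; the factor-2-free
variant is also emitted because usage differs between authors. The
extinction fishing mortality solves the low-density Euler–Lotka form
$\lambda^{\alpha} - e^{-M}\lambda^{\alpha-1} = e^{-M\alpha} \bar m$ and
equates $F_{extinct} = r_{max} = \ln \lambda_{max}$. For this stock these
give $r_Z \approx 0.074$ and $F_{extinct} \approx 0.046$ at $M = 0.239$;
the corresponding published values (0.048/0.051 and 0.254) are not
reproducible from any formulation stated with them, so the package reports
its own clearly-specified constructions and makes no claim to match.

## The synthetic catch generator

`simulate_catch()` emulates a 1980s gillnet sample whose original records
are unavailable. It draws continuous ages from the stationary exploited
age distribution — abundance $\propto e^{-Mt}$ below the knife-edge
recruitment age $t_c$ and $\propto e^{-Mt_c} e^{-(M+F)(t-t_c)}$ above,
weighted by a partial-recruitment ramp (0.25, 0.5 for the two ages below
$t_c$) — assigns VBGF lengths with multiplicative lognormal noise
(CV 0.08, chosen once so the length mode falls in the 45–55 cm bin given
the age-2 catch mode), and a 1:1 sex ratio. The canonical profile is
n = 937, M = 0.261, F = 0.395, $t_c$ = 2.

What the generator does *not* emulate, and what green tests therefore do
not establish: gear mesh selectivity beyond the simple ramp, seasonal
growth, year-class strength variation, and sampling that is not
proportional to abundance. Two measured consequences worth knowing:

* The stationary world implies ~94–96% juveniles in the catch, a little
  above the 90.6% observed historically — the real sample had a heavier
  adult tail than a stationary exploited structure allows. Tests assert
  the band the generator actually produces.
* Converting noisy lengths to ages through the inverted VBGF attenuates
  catch-curve slopes by roughly 13% at an 8% length CV (classical
  ageing-error bias). Estimator-recovery tests therefore run on the true
  recorded ages; the length-converted route is exercised for its
  qualitative behaviour only.

## Numerical and degenerate-input conventions

Ages may be fractional everywhere except in the matrix, which floors them
(a maturity age of 6.28 reproduces at the integer age 6, but
maturity-based *estimators* receive the fractional value — both are needed
to reproduce the published numbers). Lengths at or above $L_\infty$ are
unconvertible: they error in scalar calls, and in bulk composition
building they are excluded and counted, never clamped. Zero counts inside
a catch-curve limb are dropped with a warning; fewer than three usable
classes is an error. The equilibrium solver reports infeasibility when no
replacement bracket exists in (0, 3]. Draws producing invalid matrices
(possible under the zero-flooring fecundity policy) are rejected, redrawn
and counted.

## Worked example

```{r}
lh <- porosus_profile()
natural_mortality_set(lh)

mc <- run_monte_carlo(lh, porosus_uncertainty(lh), porosus_scenarios(),
                      n = 200, seed = 1)
mc$recruitment

decline_summary(mc$recruitment)$point
```

## Known limitations

Density dependence is deliberately absent (the decline projections are
density-independent extrapolations); matrices are female-only and
age-based (no stage structure, no sex structure); mortality estimators are
the classical empirical ones, not likelihood-based; and the Monte Carlo
draws components independently, with no correlation structure between
growth, maturity and mortality.
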