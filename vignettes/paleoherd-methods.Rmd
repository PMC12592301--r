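---
title: "Sex-specific mortality and herd economics from unsexed kill-off profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific mortality and herd economics from unsexed kill-off profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paleoherd)
```

This vignette is the package's account of its statistical machinery: the
two-stage Bayesian model, the sampler, the survivorship-to-yields
conversion, the synthetic-data generators that define our test conditions,
and the design choices made where the method leaves room. It states no
empirical numbers beyond what the test suite and `scripts/acceptance.R`
compute.

## Age-class schemas

Ages are in months throughout. Classes are half-open intervals
`[lower, upper)`, contiguous from 0; the convention makes contiguity checks
unambiguous. The model needs a midpoint for every class, so the open-ended
last archaeological class must be closed: `age_class_schema()` takes an
explicit `terminal_cap`, defaulting to 144 months (12 years) when the file
omits it. The cap matters twice — it sets the last midpoint `t*_T` and it is
the horizon of all monthly yield sums — and nothing in the data pins it
down, which is why it is a schema field rather than a constant. Modern and
ancient data may use different schemas; only the midpoints enter the model.

## Stage one: the modern sex-ratio regression

Survivor counts `Y_sij` (herd `i`, sex `s`, class `j`) are Poisson with a
log link; `log PS_ij` enters as an offset with coefficient fixed at 1, so
the linear predictor models survival *rates*. Herd heterogeneity is a
random intercept `eta_i ~ N(0, omega^2)`. Priors are `N(0, 10000)` on the
regression coefficients — a proper Gaussian so vague it is operationally
flat, which reconciles the two ways such priors are usually described — and
`omega ~ U(0, 100)`.

The sex ratio transferred to the ancient stage is
`r(t) = exp(beta2 + beta3 t)`. The female age slope `beta1` is fitted and
retained (posterior-predictive checks need it) but never enters `r(t)`.

**Sampler.** All conditionals of `beta` and `eta` under the Poisson
log-link are log-concave. We update them by univariate slice sampling
(stepping-out with shrinkage), which is exact for log-concave targets and
needs no envelope construction or rejection bookkeeping; `omega` moves by
random-walk Metropolis on the log scale. Chains are initialised from a
fixed-effect Poisson GLM fit, which is deterministic and puts the chain in
the typical set immediately. The default schedule is 2 chains of 110,000
iterations, 10,000 burn-in, thinning 10 — 20,000 retained draws.
Convergence reporting uses the classical two-variance Gelman–Rubin shrink
factor on 4 independent runs, lag-based autocorrelation, and trailing
rolling summaries.

## Stage two: the ancient mortality model

Death counts for site `k` are multinomial with class probabilities
`theta_k ~ Dirichlet(gamma)`; marginalising `theta` gives the
Dirichlet–multinomial likelihood used for `gamma`, whose components carry
independent `TN(0, 1000; 0, Inf)` priors. We implement the standard DM pmf
with `Gamma(n_j + gamma_j)` in the product; the variant sometimes printed
with `Gamma(n_j + gamma_+)` does not normalise (the package's enumeration
tests verify normalisation directly). When several sites are fitted
together `gamma` is shared — the hierarchical reading of
`theta_k ~ Dir(gamma)`; fitting sites separately recovers per-site
concentrations.

Sex partition: with `S_j` the total survival past class `j`,
`f_j = S_j/(1 + r(t*_j))` centrally, and `f_j` receives truncated-normal
noise with variance 0.01 — vaguely informative on a quantity bounded by
1/2 — applied independently per class (nothing suggests shared noise). The
male curve is **defined** as `m_j = S_j - f_j`, so total survival always
reconciles with the death profile and the ratio `m/f` absorbs the link
noise. The truncation interval is tightened from `(0, f_{j-1})` to
`(max(0, S_j - m_{j-1}), min(f_{j-1}, S_j))` so that both sexes'
survivorship is non-increasing *by construction*. The sex ratio at birth is
1:1 by default (`male_birth_share` is a control parameter; empirical
estimates run 51–53% male).

**Sampler.** A Gibbs scheme per iteration:

1. `(beta2, beta3)` is drawn from the stored modern posterior — *modular
   (cut) two-stage inference*. The modern regression is fitted once;
   ancient profiles, typically a few dozen individuals, are never allowed
   to distort it. A joint fit would let a 10-individual site pull on
   coefficients estimated from thousands of census records.
2. Ambiguous individuals are re-imputed, each from its candidate classes
   with probability proportional to the current `theta` (uniform when
   `theta` vanishes on the whole set — the limit of the rule).
3. Each `gamma_j` moves by random-walk Metropolis on the log scale against
   the collapsed DM likelihood and its TN prior. Step sizes are tuned to
   20–40% acceptance during burn-in in blocks of 100 iterations, then
   frozen so the post-burn-in kernel is fixed.
4. The `(theta_k, f_k)` block is drawn **exactly**: `theta_k ~
   Dirichlet(gamma + n_k)` by conjugacy, then `f_k` from its sequential
   truncated-normal conditional, `m_k = S_k - f_k`. No other likelihood
   term involves `f`, so the joint conditional factorises and no
   Metropolis correction is needed. (An independence-proposal MH version
   of this update, correcting for the f-link, is valid but mixes
   catastrophically — the current `f` pins `theta` to a thin band and
   almost every proposal is rejected; the exact block draw has the same
   stationary distribution and none of that pathology. A prior-only run
   with fixed `gamma` reproduces Dirichlet moments to Monte-Carlo
   accuracy, which is the regression test for this property.)

Degenerate truncation intervals (zero width, e.g. when `S_j = 0`) collapse
to their bound and are treated as point masses. Truncated-normal draws use
the inverse-CDF method, adequate at sd 0.1 scales; far-tail intervals
return the bound nearest the mean.

The deterministic map `survival_from_theta()` reports *central* values and
clips only to `[0, min(f_{j-1}, S_j)]` — the female constraint. Extreme
sex-ratio configurations can make the implied `m` locally increasing
there; the sampler's tightened truncation is what enforces male
monotonicity, and the map flags every clipped class.

## From survival curves to yields

Survivorship attaches to the *upper boundary* of each class — `f_j` is
"still alive in class j" — with knots `(0, 1/2)`, `(upper_j, f_j)`,
`(cap, 0)` linearly interpolated at integer months. Month `x` spans ages
`x` to `x+1`: alive-weighted sums (milk, births, feed) use survival at the
month's start, deaths during month `x` are `s(x) - s(x+1)` and are
slaughtered at the month-end weight `nu(x+1)`.

Weight-by-age is `nu(x) = tau exp((a/b)(1 - e^{-bx}))`, fitted to weight
data by box-constrained least squares (`tau` in [10, 30], `a, b` in
(0, 1]) over a fixed multi-start grid with an L-BFGS-B polish —
deterministic, with a flag when a bound binds. The package default
`(tau = 22, a = 0.15, b = 0.08)` describes a small unimproved animal
(asymptote ≈ 143 kg); `inst/extdata/synthetic_growth_weights.csv` is a
synthetic table generated from exactly this curve, for examples and CLI
use.

Calving-cycle structure is collapsed to steady-state monthly rates
(`derive_constants()`): milk per cow-month `42.3 x 9.18 / 18.36 ≈ 21.15`
kg (the value usually quoted, 21.13, reflects rounding in intermediate
averages; we report the computed number), available milk after the calf's
68.4%, birth probability `1/18.36 ≈ 0.0545` per month past first calving
at 42 months, and feed `2.475%/day x 365.25/12 ≈ 75.33%` of live weight
per month. Milk accrues to every female month past first calving — exactly
the collapse of cycle structure into a per-cow-month average. Herd growth
counts births per animal born, both sexes in the denominator through the
1/2 birth shares. Efficiency (kcal per kg feed) is a *relative* index for
comparing strategies; the feed proxy is not a nutritional model.

All yields are linear in each per-kg density constant (a perturbation test
asserts this), so absolute levels inherit any bias in the ethnographic
constants while cross-strategy comparisons are stable.

## Synthetic data: what the generators emulate

The **modern census generator** draws `eta_i ~ N(0, omega^2)` and Poisson
counts from the model's own linear predictor, capped at the population
size with a warning counter. Our fixture — `beta = (-0.02, -0.3, -0.01)`,
`omega = 0.2`, 15 herds, 500 head per cell — mimics the scale of real
unimproved-herd census collections. It uses a triennial 4-class census
schema (0–36–72–108–144): with fine classes the first midpoint sits at
half a month, where female survival is essentially 1, and the cap then
truncates the Poisson likelihood often enough to visibly distort
calibration; with 3-year bins the cap is almost never reached and
simulate–refit coverage is clean. Broad bins are also what herd censuses
actually report. What the generator does *not* emulate: age-estimation
error in censuses, non-Poisson clustering, and culling rules that change
over calendar time.

The **kill-off generator** draws multinomial counts from a known `theta`
and can blur individuals into adjacent-class candidate sets at a given
rate, emulating fragmentary ageing. Real MNI profiles additionally carry
inter-observer and taphonomic structure that no multinomial captures, so
passing recovery tests here demonstrates correctness of the inference, not
robustness to archaeological bias.

## Validation protocol

Truths are drawn jointly — `(gamma, beta2, beta3)` from a reference
ancient fit, `theta ~ Dir(gamma)`, then `f` through the same
truncated-normal link the model assumes — and one multinomial count vector
is drawn per sample size. The full design is 50 truths by sizes
{10, 20, 50, 75, 100, 150, 200}: 350 profiles. Empirical coverage of the
HPD intervals of `f` (shortest-window method, ties to the lowest start) is
tabulated by size and class. The package's routine checks run a scaled
protocol — 10 truths, sizes {20, 200}, single chains of 11,000 iterations
(1,000 burn-in, thin 10) — chosen so the whole suite runs in minutes on
one CPU while still detecting miscalibration of ±10 percentage points;
`scripts/acceptance.R` recomputes it from scratch. The full paper-scale
protocol is the same code with the default arguments.

## Strategy search

Random kill-off strategies come in two flavours: *sex-asymmetric* draws
`(f, m, r)` from the posterior predictive of a reference fit (the model's
own notion of a plausible sexed strategy), and *sex-symmetric* draws class
proportions `psi ~ Dir(1)` and kills both sexes as `psi/2`. Default
`n_sims` is 20,000 (the protocol's figure; one passage quotes 100,000 —
the parameter is configurable precisely because the two statements
differ). Strategies can be conditioned on herd growth > 1; the
Pareto-optimal subset on (efficiency, herd growth) is reported and is
invariant to simulation order.

One qualitative claim deserves a caveat. Among growth-conditioned
sex-asymmetric strategies, whether the *majority* shows higher milk than
MOW efficiency is highly sensitive to conditions the method itself does
not fix: the terminal cap (how long surviving females keep milking before
their terminal carcass weight is booked to MOW) and the calving
parameters. Under this package's defaults (cap 144, unimproved-herd
constants) the conditioned majority favours MOW — the acceptance suite
computes and reports the fraction rather than assuming it. Shorter calving
intervals, earlier first calving, or a longer female maximum age all move
the balance toward milk.

## Numerical choices and degenerate inputs

* Log-gamma space for every DM term; enumeration tests confirm the pmf
  sums to 1 on small lattices.
* HPD by empirical shortest window, `ceiling(mass * n)` draws, ties to the
  lowest start; degenerate (constant) draws give zero-width intervals.
* Gelman–Rubin in the classical two-variance form; zero within-chain
  variance reports a flagged `NA` rather than erroring.
* Dirichlet draws via normalised gammas with an argmax fallback for
  underflow at tiny concentrations.
* Profiles with zero individuals are rejected unless explicitly allowed
  (`.allow_empty`), which exists for prior-predictive runs.
* All fits are exactly reproducible from an integer seed; chain `c` uses
  `seed + c - 1`.

## Known limitations

The sex-ratio transfer assumes ancient culling followed the same
age-pattern of male removal as modern unimproved herds — the central,
untestable assumption. Yields inherit the ethnographic constants wholesale;
they are defensible for comparing strategies, not for absolute prehistoric
production estimates. The feed proxy prices every kilogram of animal
equally. MNI derivation from tooth inventories is out of scope: the tool
consumes finished profiles, and nothing corrects for recovery or
identification bias upstream of them.
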