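# paleoherd

Bayesian inference of **sex-specific cattle survival curves from unsexed
archaeological kill-off profiles**, and of the lifetime product yields those
survival curves imply.

## The problem

Zooarchaeologists age cattle remains from tooth eruption and wear, producing
*kill-off profiles*: MNI death counts over ordered age classes. Milk yield,
herd growth and the economics of a slaughter strategy all hinge on
*sex-specific* survival, but faunal assemblages can almost never be sexed.
Censuses of modern unimproved herds, however, show a strong, regular decline
of the male:female ratio with age — males are culled young, females kept for
breeding and milk. `paleoherd` borrows that age-dependent sex-ratio signal
to partition unsexed mortality by sex, with full posterior uncertainty.

## The model

**Modern stage.** Survivor counts in modern herd censuses follow a Poisson
regression with a log-population offset and herd random effects:

    Y_sij ~ Poisson(mu_sij)
    log mu_sij = eta_i + log PS_ij + beta1 t_j + beta2 Sex_si + beta3 Sex_si t_j
    eta_i ~ N(0, omega^2),  beta ~ N(0, 10000),  omega ~ U(0, 100)

yielding a posterior over the sex ratio `r(t) = exp(beta2 + beta3 t)`
(males per female alive at age `t` months).

**Ancient stage.** Death counts `N_k` over `T*` classes are
Dirichlet–multinomial, `N_k ~ DM(gamma)` with
`gamma_j ~ TN(0, 1000; 0, Inf)`. Writing `S_j = 1 - theta_1 - ... - theta_j`
for total survival past class `j`, female and male survivorship satisfy

    f_j = S_j / (1 + r(t*_j)),   m_j = S_j - f_j,
    f_0 = m_0 = 1/2,             f_T* = m_T* = 0,

with a truncated-normal link (sd 0.1) around the central `f_j` that lets the
ratio `m/f` wobble around `r` while the accounting identity `m = S - f` is
preserved exactly. Individuals aged only to a run of adjacent classes are
imputed inside the MCMC. The per-class *male excess kill* is
`(m_{j-1} - m_j) - (f_{j-1} - f_j)`.

**Economics.** Per posterior draw, survivorship is interpolated to monthly
resolution and combined with a Gompertz-type growth curve
`nu(x) = tau exp((a/b)(1 - e^{-bx}))` and ethnographic constants for
unimproved herds (milk 42.3 kg/month while suckling, 18.36-month calving
interval, first calving at 42 months, 68.4% of milk to the calf, MOW = 49.95%
of live weight, feed 2.475% of live weight/day, USDA nutrient densities) to
give lifetime milk, meat-and-offal, protein, fat and calorie yields, a
feed-weight cost proxy, herd growth (animals per animal born) and the
*relative* economic efficiency of calorie production (kcal per kg feed).

## Worked example

Simulate a modern census and an unsexed kill-off profile, then run the full
chain (synthetic data, so the truth is known):

```r
library(paleoherd)

census <- age_class_schema(lower = seq(0, 108, 36), upper = seq(36, 144, 36))
tab <- generate_modern_synthetic(c(-0.02, -0.3, -0.01), 0.2, 15, census,
                                 500, seed = 1)
mfit <- fit_modern(tab, sampler_schedule(3000, 600, 4, 2), seed = 2)
mfit
#> Modern sex-ratio posterior: 1200 draws, 15 herds
#>   beta1   beta2   beta3   omega
#> -0.0197 -0.2842 -0.0101  0.2169
```

The posterior recovers the generating coefficients; the implied sex ratio
falls from 0.71 males per female at 6 months to 0.40 at 63 months.

```r
prof <- generate_killoff_synthetic(
  c(0.02, 0.04, 0.06, 0.10, 0.08, 0.10, 0.30, 0.20, 0.10), 200,
  legge_schema(), site_id = "demo", seed = 3)
afit <- fit_ancient(prof, mfit, sampler_schedule(11000, 1000, 10, 2), seed = 4)
afit
#> Ancient mortality posterior: 2000 draws, 1 site(s) [ demo ]
#>   demo posterior mean f: 0.493 0.467 0.440 0.400 0.363 0.318 0.180 0.064
subset(summarize_ancient(afit), param == "f" & class %in% c(1, 6))
#>    site param class  mean median hpd_low hpd_high
#> 19 demo     f     1 0.493  0.495   0.480    0.500
#> 24 demo     f     6 0.318  0.318   0.221    0.412
```

`f` is the proportion of the birth cohort that is female and still alive in
each class (at most 1/2): here 31.8% (95% HPD 22–41%) of animals born are
females alive in the 36–48-month class — the milking herd.

```r
y <- yields_over_posterior(afit, default_growth_params())
subset(summarize_yields(y),
       output %in% c("milk_kg", "mow_kg", "herd_growth", "efficiency"))
#>         output      mean    median   hpd_low hpd_high
#> 1      milk_kg 9.642e+01 9.666e+01 5.474e+01   137.46
#> 3       mow_kg 6.287e+01 6.290e+01 6.092e+01    64.77
#> 9  herd_growth 7.857e-01 7.877e-01 4.461e-01     1.12
#> 10  efficiency 3.799e+01 3.801e+01 3.270e+01    43.06
```

Per animal born, this profile yields ~96 kg of milk and ~63 kg of
meat-and-offal over a lifetime, a herd growth rate of 0.79 (below
replacement under the unimproved-herd constants) and ~38 kcal per kg of
feed. Efficiency is a relative measure for comparing strategies, never an
absolute cost. `search_strategies()` explores random kill-off strategies
under sex-asymmetric and sex-symmetric scenarios and reports the Pareto
front on (efficiency, herd growth); `simulate_validation_suite()` plus
`coverage_report()` run the simulate–refit HPD-coverage validation.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/paleoherd fit-modern --table census.csv --schema schema.txt \
    --iters 110000 --burnin 10000 --thin 10 --chains 2 --seed 1 --out draws.csv
```

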