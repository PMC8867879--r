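# leadtimesim

Microsimulation of the **lead-time bias** that mammography screening induces
in relative-survival based prognosis metrics: 10-year relative survival,
**loss in life expectancy (LLE)** and **proportion of life lost (PLL)**.

Lead time is the interval between screen detection of a tumour and the time
it would have been diagnosed symptomatically. Measuring prognosis from
diagnosis therefore makes screened populations look better even when nobody's
death is delayed. `leadtimesim` isolates that artefact by simulating a female
population with a known breast-cancer natural history, fixing each woman's
death age once, imposing screening scenarios of varying sensitivity and
attendance on the *same* latent histories, and comparing estimates with and
without screening. It is aimed at cancer epidemiologists and biostatisticians
who report LLE/PLL for screened cancers and need to know how much of a
group or calendar-time difference lead time alone can produce.

## The model

All-cause mortality is decomposed in the relative-survival framework,
`h(t) = h*(t) + λ(t)`, with `h*` the expected rate from a population life
table and `λ` the excess rate. Estimation uses a flexible parametric
(Royston–Parmar-type) relative-survival model

```
log Λ(t | age) = s(log t | γ, k0) + α·age + age·s_tvc(log t | δ)
```

with a df-3 restricted-cubic-spline baseline and a df-3 time-dependent age
effect, fitted by maximum likelihood with the expected rate at each exit
time. Marginal metrics are externally age-standardised with ICSS weights
(7/12/23/29/29% for ages ≤44, 45–54, 55–64, 65–74, ≥75), and

```
LLE = ∫ S*(t) dt − ∫ S*(t) R(t) dt   (0 to t_max = 100 − age),
PLL = LLE / ∫ S*(t) dt.
```

The simulation follows the published design: birth cohorts 1870–1965,
tumour onset by age-specific probabilities, exponential tumour-volume growth
with gamma-distributed inverse growth rates, volume-proportional symptomatic
detection, other-cause death from life tables by the inversion method
(capped at age 100), cancer death from a generating FPM clocked at the
latent symptomatic age, biennial screening invitations at ages 40–74 with
logistic size-dependent sensitivity (0.58 / 0.84 / 0.96 at 12 mm for the
low / moderate / high scenarios) and perfect or imperfect (80% @ 0.9 +
20% @ 0.15) attendance, a 1970–1974 diagnosis window and 12-year
administrative censoring. See `vignettes/lead-time-bias.Rmd` for the full
methods account.

## Worked example

The desk-scale profile (500 women per birth cohort, 20 replicates; the
full-scale profile uses 10,000 and 200):

```r
library(leadtimesim)
cfg  <- default_config(fast = TRUE)
est  <- run_experiment(cfg, seed = 1234)
bias <- compute_bias(est)
```

Per-scenario averages over the 20 replicates:

```
           scenario      n median_age pct_screen lead_mean  rs10   lle   pll
               none 141.10     62.601      0.000       NaN 0.480 7.942 0.455
        low_perfect 142.65     61.993     35.517     1.652 0.485 7.825 0.446
   moderate_perfect 144.25     61.566     47.299     2.053 0.493 7.769 0.441
       high_perfect 147.40     61.377     57.116     2.484 0.500 7.679 0.432
      low_imperfect 142.30     62.053     28.018     1.655 0.482 7.878 0.449
 moderate_imperfect 143.80     61.794     37.342     2.045 0.482 7.867 0.448
     high_imperfect 145.85     61.392     45.844     2.433 0.492 7.768 0.438
```

Screening never changes a death age, yet the diagnosed cohorts grow, get
younger, and their estimated 10-year relative survival (`rs10`) rises while
LLE (years) and PLL fall — pure lead time. The bias table quantifies it
(`bias` = mean difference to no screening, `mcse` its Monte Carlo SE,
`rel_bias` in %):

```
           scenario metric     bias   mcse rel_bias
        low_perfect   rs10  0.00523 0.0047    1.220
   moderate_perfect   rs10  0.01320 0.0063    3.070
       high_perfect   rs10  0.01940 0.0087    4.340
        low_perfect    lle -0.11700 0.0940   -1.100
   moderate_perfect    lle -0.17300 0.0970   -1.710
       high_perfect    lle -0.26300 0.1200   -2.830
      low_imperfect    lle -0.06400 0.0820   -0.428
 moderate_imperfect    lle -0.07470 0.0970   -0.488
     high_imperfect    lle -0.17400 0.1000   -1.680
```

Relative survival is biased upwards and LLE downwards; the magnitude grows
with screening sensitivity and shrinks under imperfect attendance. At this
reduced scale the pattern (signs and orderings) is the result; absolute
magnitudes depend on natural-history parameters that are configurable
stand-ins.

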