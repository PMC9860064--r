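# cocultx

Growth and mortality curve analysis for long-term phototroph–heterotroph
co-cultures.

Marine *Prochlorococcus* (a cyanobacterial primary producer) survives
long-term nitrogen starvation when co-cultured with heterotrophic
*Alteromonas*, and the clearest signature of that interaction is not in the
growth phase of a batch culture but in the **decline phase** of its bulk
chlorophyll fluorescence curve. `cocultx` packages the full quantitative
workflow for such experiments, for microbial ecologists working with
near-daily fluorescence time series (~140 days per batch) and flow-cytometry
cell counts at a few sampled days:

- **Growth features** — log-linear regression on the exponential phase,
  `ln(N_t) = ln(N_0) + mu (t - L)`, giving growth rate `mu` (per day), lag
  `L` (days) and the peak `(FLmax, tmax)`; windows are accepted only at
  r² > 0.9.
- **Mortality models** — four descriptive laws fitted to the peak-normalized
  decline `y(tau) = FL(tmax + tau) / FLmax`:

  | model | form | free parameters |
  |---|---|---|
  | exponential | `y = exp(-a tau)` | 1 |
  | bi-exponential | `y = f exp(-a1 tau) + (1-f) exp(-a2 tau)` | 3 |
  | harmonic | `y = 1 / (1 + a tau)` | 1 |
  | Weibull | `y = exp(-a tau^n)` | 2 |

  fitted by bounded multi-start least squares under a smooth-L1 robust loss
  (scale 0.1), compared by RMSE and Gaussian BIC. The Weibull shape `n`
  separates accelerating mortality (`n > 1`, damage accumulation) from
  decelerating mortality (`n < 1`, acclimation), and the decimal reduction
  time `td = (ln(10^d)/a)^(1/n)` gives the days needed for a `d`-decade
  decline (`td2` = two decades).
- **Nitrogen budgets** — flow-cytometry counts converted to biomass through
  cellular N quotas, `biomass [umol N/L] = X [cells/ml] * Q_N [fg/cell] *
  1e-6 / MW_N`, carrying-capacity feasibility against the 100 umol/L N
  supply, and synergy classification by log2 fold change of a population's
  biomass in co-culture vs its axenic control.
- **Curve-shape analytics** — peak-aligned daily matrices (days −10..+80
  relative to the peak), PCA ordination, distance-based PERMANOVA
  (pseudo-F, R², permutation p), and random-forest strain classification
  with per-day feature importance.
- **Synthetic data** — a generator for the full 5 × 5 strain grid plus
  axenic controls with known ground truth, so every stage of the pipeline is
  testable without the original measurements.

## Worked example

```r
library(cocultx)
es <- simulate_experiment(sim_config(seed = 7))
es
#> <experiment_set>
#>   105 cultures with curves (14805 observations), 105 metadata rows
#>   treatments: axenic_alt=15, axenic_pro=15, coculture=75
#>   counts: 540 records on day(s) 60, 100, 140

curve <- get_curve(es, "E1_NATL2A_AltDE1_r1")
fit_growth(curve)
#> <growth_fit>
#>   mu = 0.6048 /day, lag = 1.83 days, r2 = 0.9993
#>   peak 402 au at day 9.09; window points 3..10

phase <- extract_decline(curve)
fit_all_models(phase, seed = 7)
#> <decline_fit_all>
#>   exponential    rmse = 0.0635  bic = -722.9
#>   biexponential  rmse = 0.01459  bic = -1101
#>   harmonic       rmse = 0.03211  bic = -902.9
#>   weibull        rmse = 0.00382  bic = -1460
#>   best by RMSE: weibull; best by BIC: weibull
```

The growth fit says this co-culture grew at 0.60 per day after a 1.8-day
lag and peaked at 402 fluorescence units on day 9. Among the four mortality
laws the Weibull fits its decline best (RMSE 0.004 on the normalized scale)
with shape `n = 0.26 < 1` — the death rate *decreases* as starvation
proceeds — and a two-decade reduction time of about 264 days, the signature
of a heterotroph-supported co-culture; an axenic culture typically shows
`n > 1` and `td2` near 13 days.

The whole analysis (features → mortality fits → budgets and synergy →
ordination, PERMANOVA, classification → correlations) runs as one call:

```r
report <- run_pipeline(es, seed = 7, out_dir = "results")
report
```

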