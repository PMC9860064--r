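---
title: "Modelling growth and mortality in phototroph-heterotroph co-cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling growth and mortality in phototroph-heterotroph co-cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocultx)
```

## The system and the data

A batch co-culture of a marine cyanobacterium (*Prochlorococcus*) and a
heterotrophic bacterium (*Alteromonas*) in low-nitrogen seawater medium
grows exponentially for about a week, peaks when the ~100 µmol/L of
inorganic N is exhausted, and then declines for months. Bulk chlorophyll
fluorescence, measured near-daily in arbitrary units, tracks the phototroph
population; the heterotroph is invisible to it and is counted by flow
cytometry on a few sampled days. The scientific signal of interest is the
*shape of the decline*: axenic phototroph cultures crash within weeks,
co-cultures decline slowly and survive for over a year, and which partner
drives the difference is a strain-level question.

`cocultx` implements the complete analysis: growth-phase parameters, four
competing mortality models, nitrogen-quota biomass accounting, and
shape-level ordination/classification, plus a synthetic-data generator that
emulates the study design with known ground truth.

## Growth-phase model

Fluorescence on the exponential segment follows
$N_t = N_0\,e^{\mu (t - L)}$, fitted as ordinary least squares of
$\ln FL_t$ on $t$. The window is found by anchoring at the fluorescence
peak (ties broken to the earliest day, so the decline phase starts as early
as possible) and shrinking from the front to drop lag points. A window is
accepted when r² > 0.9 with positive slope. Two refinements keep lag
points out of windows that would still clear the r² bar:

- shrinking continues while dropping the leading point improves r² by more
  than 0.005, and
- a leading point whose residual exceeds 3× the standard deviation of the
  remaining residuals is dropped.

On noiseless data these rules recover the generating rate exactly; with 5%
multiplicative noise the rate is recovered within ±0.05 in ≥95% of curves
(tested at µ = 0.4/day, 15 points). The lag is defined through the
intercept, $L = (\ln FL_{\text{first}} - b)/\mu$ clipped at 0, with
$FL_{\text{first}}$ the first observed positive fluorescence — the simplest
definition consistent with the growth equation; a threshold-crossing
definition would be a reasonable alternative, and the choice is recorded so
the two can be compared.

One discretization caveat, a property of peak-anchored windows rather than
of the regression: with daily sampling, the *observed* peak can sit a
fraction of a day past the true growth-decline corner, on the first decline
sample. For decelerating (co-culture-like) declines that point is well
below the exponential line and is effectively excluded; for accelerating
(axenic-like) declines the first day of decline is nearly flat, the
observed peak lands there, and the recovered rate is accurate to a few
percent rather than machine precision.

## Mortality models

The decline is analysed on normalized fluorescence
$y(\tau) = FL(t_{\max} + \tau)/FL_{\max}$, $\tau$ in days since the peak,
so $y(0) = 1$ by construction, RMSE is comparable across cultures, and
$FL_{\max}$ is fixed at the observed peak, never a free parameter. Four
laws are fitted:

| model | $y(\tau)$ | parameters | interpretation |
|---|---|---|---|
| exponential | $e^{-a\tau}$ | $a$ | constant per-capita death rate |
| bi-exponential | $f e^{-a_1\tau} + (1-f) e^{-a_2\tau}$ | $f, a_1, a_2$ | two subpopulations with distinct rates |
| harmonic | $1/(1 + a\tau)$ | $a$ | quadratic (encounter-driven) mortality |
| Weibull | $e^{-a\tau^n}$ | $a, n$ | heterogeneous stress tolerance |

The Weibull shape $n$ is the headline statistic: $n > 1$ means the
instantaneous death rate rises over time (damage accumulation), $n < 1$
that it falls (acclimation, or selection of resistant cells). The
decimal-reduction time is
$t_d = (\ln 10^d / a)^{1/n}$; `weibull_td()` guarantees
$y(t_d) = 10^{-d}$ to 1e-10 relative accuracy. The Weibull curve can be
written equivalently in rate form $e^{-a\tau^n}$ (used for fitting) or
scale form $e^{-(\tau/a')^n}$ with $a' = a^{-1/n}$ (`weibull_scale()`);
$t_d$ is invariant to the choice.

### Fitting

`fit_decline()` minimizes a smooth-L1 (soft-L1) robust loss,
$\rho(r) = 2 s^2 (\sqrt{1 + (r/s)^2} - 1)$ with scale $s = 0.1$, under box
bounds (rates in [0, 50] per day, $n \in [0.01, 10]$, $f \in [0,1]$) by
L-BFGS-B with analytic gradients. The robust loss damps the influence of
"second growth" excursions; the reported RMSE always uses plain residuals,
so goodness of fit is defined independently of the loss.

The landscape is multimodal (most visibly the $a_1 = a_2$ ridge of the
bi-exponential, a stationary set that symmetric starts can never leave),
so fitting is multi-start: the all-0.5 vector plus 50 random starts, the
winner chosen by lowest RMSE with ties to the earlier start. Random starts
draw the fraction $f$ uniformly but rates and shape *log-uniformly* across
their bounds: decay rates live on [0.01, 1] per day while the bound spans
[0, 50], and uniform draws land almost surely in the flat large-rate region
from which gradient descent cannot escape (in direct measurement, 0/200
uniform starts reached the bi-exponential optimum vs 27% of log-uniform
ones, making 50 starts essentially certain). The winning start is polished
with a tight-tolerance refit. All randomness is seeded; the same seed gives
bit-identical fits, and the caller's RNG state is never disturbed.

On noiseless data each generating model is recovered to 1e-4 (the
bi-exponential up to its inherent $(f,a_1) \leftrightarrow (1-f,a_2)$ label
swap, resolved by reporting $a_1 \ge a_2$).

### Model comparison

Models are ranked by RMSE and by Gaussian BIC,
$m \ln(\mathrm{RSS}/m) + k \ln m$, with $k$ the free-parameter count
(1/3/1/2). Two degenerate cases need care: an exactly zero RSS returns a
$-\infty$ sentinel flagged `perfect_fit`, and the residual variance is
floored at $10^{-12}$ (RMSE $10^{-6}$ on the normalized scale, far below
any real measurement) so that among numerically perfect fits the
parameter-count term decides — on noiseless exponential data the
exponential, Weibull and bi-exponential all fit to machine precision and
the 1-parameter exponential correctly wins.

Below-detection points (fluorescence at or below the detection floor) are
excluded from fitting rather than clamped; clamping would fabricate a
plateau in arbitrary units and bias the shape estimate.

## Nitrogen budgets and synergy

Counts convert to biomass as
$X\,[\text{cells/ml}] \times Q_N\,[\text{fg N/cell}] \times 10^{-6} / MW_N$
µmol N/L. Default quotas: 7 fg N/cell for high-light phototroph strains
(MED4, MIT9312, MIT0604), 10.5 for NATL2A, 14 for MIT9313, 13 for all
heterotroph strains — deliberately at the low end of measured values (which
reach ~20 and ~25 fg under replete growth), since cells under long-term N
stress hold less N and higher quotas would imply more biomass N than the
100 µmol/L supplied. `quota_sensitivity()` maps the feasibility region of
that assumption; biomass is linear in each quota, so the boundary is
monotone.

Synergy is the log2 fold change of a population's biomass in co-culture
over its same-strain axenic control (same-strain pairing is assumed; the
alternative of a pooled control is a one-line change). Significance uses
pairwise t-tests on log2 biomass, Bonferroni-multiplied by the number of
strain pairs tested that day. Within `synergy_analysis()` the tests share
the pooled within-arm variance across all arms of the day (the ANOVA
residual, df = N − k), as in Bonferroni-corrected ANOVA pairwise testing:
with triplicate arms, two-sample Welch tests have ~3 degrees of freedom and
cannot detect even 2.5-fold changes after a 25-fold correction, whereas the
pooled test has the power of the full design. A significant positive fold
change is called synergistic, significant negative competitive, anything
else neutral (with a `negative_trend` flag for non-significant negative
trends, the "potentially competitive" reading).

## Curve-shape analytics

For shape-level questions each curve is aligned so its peak is day 0,
binned into half-open one-day bins $[d, d+1)$ over days −10..+80 (91
features), averaging within bins, linearly interpolating interior gaps and
extending edges with the nearest observed value; columns are then
standardized to mean 0 and *population* (divisor n) unit variance, constant
columns set to 0 and flagged. "Max growth point" is read as the day of peak
fluorescence, consistent with the decline anchoring.

- **PCA** on the standardized matrix, with each component's sign fixed by
  making its largest-magnitude loading positive, so ordinations are
  deterministic across runs and platforms.
- **PERMANOVA** on the Euclidean distance matrix: sums of squares from the
  Gower decomposition of squared distances, pseudo-F =
  $(SS_B/(k-1))/(SS_W/(N-k))$, and a permutation p with the +1 convention
  ($p \ge 1/(n_{perm}+1)$; p can never be 0). The implementation is checked
  against exhaustive enumeration on 6-sample instances and against
  `vegan::adonis2` for F and R².
- **Random forest** classification of curves by phototroph or heterotroph
  strain: stratified 10-fold cross-validation (folds reduced with a warning
  when a class is smaller), with per-day importance (mean decrease in Gini
  impurity) averaged over 30 refits on the full matrix. Whether the
  original cross-validation was stratified is not knowable from the
  outside; stratification is the choice here because unstratified folds on
  15-member classes can be accidentally class-free.

## The synthetic-data generator

`simulate_experiment()` generates the full design — 25 phototroph ×
heterotroph combinations plus 5 + 5 axenic controls, in triplicate — with
every generating parameter recorded, so pipeline accuracy is measurable.
Its defaults are the study conditions: 140 days of daily sampling with
±0.15-day jitter, 5% multiplicative lognormal noise (fluorescence is
positive and errors scale with signal), a detection floor of 1 au (values
below it are reported at the floor and flagged), and counts at days
60/100/140.

Strain profiles draw their mortality parameters around the study-scale
group statistics: axenic Weibull shape ~N(2.1, 0.9) clipped above 1.1 with
td2 ~N(12.6, 3.9) days; co-culture shapes below 1, with synergistic strains
~N(0.36, 0.14) and competitive strains ~N(0.52, 0.16) (pooling to ~0.4) and
td2 lognormal around 316 days. One phototroph profile (MIT9313-like)
carries a 10-day co-culture lag penalty, the "delayed growth" phenotype;
heterotroph identity deliberately has no effect on the phototroph's decline
law, which is the null the classification asymmetry test must detect.
Counts are generated *budget-downward*: expected per-population N biomass
first (anchored to the day-60/100/140 group levels: co-cultures ~70,
axenic heterotrophs ~32 µmol N/L, heterotroph fraction ~0.8, phototroph
benefit log2FC ~10, heterotroph benefit ~1.3 for synergistic vs ~−0.2 for
competitive strains, ~1% of N in biomass by day 140), rescaled if needed to
keep totals within the 100 µmol/L supply, then converted to cells through
the quotas — so the closed-N-budget invariant and the quota round trip hold
by construction. An optional "second growth" term (log-space Gaussian bumps
~45 and ~100 days after decline onset, off by default) reproduces the
non-monotonic declines of strongly recycling co-cultures for
misfit-correlation analyses.

What the generator does *not* emulate: real second-growth timing
variability, slow drift of the detection floor, culture crashes or
contamination, replicate-level parameter variation beyond measurement noise
(replicates share their strain's true parameters), and any mechanistic
nutrient dynamics — trajectories are piecewise closed forms, not ODE
solutions. Passing tests therefore demonstrate the *statistical machinery*
(recovery, ranking, discrimination) under the study's noise and design,
not that real curves follow these laws.

## Numerical choices, in one place

- Peak ties → earliest day. Day bins $[d, d+1)$. Growth window ≥ 4 points
  (r² on 3 points is uninformative).
- Optimizer bounds: rates [0, 50]/day, $n \in [0.01, 10]$, $f \in [0, 1]$;
  soft-L1 scale 0.1; 50 random starts (log-uniform rates); RMSE tie-break
  to the earlier start; polish refit at tight tolerance.
- BIC variance floor $10^{-12}$; zero-RSS sentinel $-\infty$.
- Shape classes: accelerating ($n > 1$), decelerating ($n < 1$), constant
  (|n − 1| ≤ 0.05).
- td2 statistics are computed per curve and then averaged (not from
  averaged parameters).
- PERMANOVA p uses the +1 convention; PCA signs fixed by
  largest-|loading|-positive.
- All stage seeds derive deterministically from one base seed
  (`seed`, stage index), so `run_pipeline()` reports are identical across
  runs with the same inputs and seed.

## Problem sizes

The default simulated design (105 cultures, ~14,800 observations) runs
through the full pipeline in well under a minute on a single core. The test
suite uses that design for group-level checks and scaled-down ensembles
elsewhere — 100-curve fitting ensembles, 200-replicate null-distribution
checks, 50-run synergy recovery — chosen to make distributional claims
testable in seconds each.

## Known limitations

- The decline is anchored at the global fluorescence peak; cultures whose
  fluorescence plateaus before declining get their early plateau counted as
  decline. Alternative onset rules would need a changepoint criterion.
- RMSE is computed on normalized fluorescence; comparisons against values
  computed on raw fluorescence require rescaling by each curve's peak.
- Growth-rate recovery is limited by daily sampling around the peak (see
  the discretization caveat above).
- With triplicates, the pooled-variance synergy test assumes comparable
  within-arm variance on the log2 scale across arms; badly heteroscedastic
  arms would need a Welch-Satterthwaite variant.
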