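---
title: "Prioritising wetlands in a boom-bust river system: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising wetlands in a boom-bust river system: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetlandprior)
```

## The problem

Dryland river basins alternate between *boom* years, when high flows flood
large wetland areas and waterbirds disperse and breed, and *bust* years,
when most habitat dries and birds concentrate on the few wetlands that
still hold water. A conservation plan built from a single snapshot of such
a system misses half of its dynamics: the wetlands that matter in a drought
are not the ones that matter in a flood. `wetlandprior` implements a
prioritisation workflow designed for this setting: minimum-set reserve
selection with per-species abundance targets, selection-frequency
irreplaceability, separate prioritisation of every survey year, wet/dry
phase analytics with a refugia/breeding classification, and a
model-averaged regression analysis of the hydrological drivers.

## Minimum-set selection

A scenario is a species-by-planning-unit count matrix $a_{si}$ with PU
costs $c_i$ (constant by default, so cost = number of wetlands) and a
representation target $p \in (0, 1]$. The target for species $s$ is
$T_s = p \sum_i a_{si}$, and a feasible reserve $S$ satisfies
$\sum_{i \in S} a_{si} \ge T_s$ for every $s$. The solver minimises

$$\sum_{i \in S} c_i \;+\; \mathrm{SPF} \sum_s \frac{\max(0,\, T_s -
\textstyle\sum_{i \in S} a_{si})}{T_s}\, b_s,$$

where $b_s$ is the greedy cost of covering species $s$ alone from the
empty set. Scaling each shortfall by $b_s / T_s$ makes the penalty
commensurate with cost units regardless of how abundant a species is; the
species penalty factor (SPF, default 100) then only needs to be "large
enough", because a repair pass (greedy additions to feasibility, then a
least-useful-first prune) guarantees that every returned solution is
feasible and irredundant no matter how the annealing run ended.

Three solvers share this objective:

* `greedy_minset()` — adds the PU with the greatest summed fractional
  unmet-target contribution per unit cost, then reverse-prunes. Ties break
  to the lowest `pu_id` so results are deterministic.
* `exact_minset()` — exhaustive search over the PUs that hold any counts,
  returning one optimum *and all co-optimal sets*. It exists as an oracle
  for testing and for tie-break-free irreplaceability arguments; it is
  intended for instances of roughly 20 nonzero PUs or fewer.
* `anneal_minset()` — single-PU flip moves with Metropolis acceptance.
  The initial temperature is set adaptively so a move of the median
  absolute size (probed over 100 random flips) is accepted with
  probability 0.8, cooling is geometric down to $10^{-5}$ of the initial
  temperature, and the best state visited is returned before repair.

### Numerical choices

Targets at fractions like 0.1 are hostile to floating point:
$0.1 \times 100$ is not representable, and `held >= target` can miss at
the boundary. The target fraction is therefore rationalised by continued
fractions ($p = \mathrm{num}/\mathrm{den}$, denominator $\le 10^6$) and
feasibility is tested as
$\mathrm{held} \cdot \mathrm{den} \ge \mathrm{total} \cdot \mathrm{num}$,
which is exact in doubles for integer counts. Shortfalls are computed on
the same integer scale, so a feasible set has *exactly* zero penalty.

The annealer draws all randomness from R's RNG (`set.seed(seed)` before
the compiled core runs), so a fixed seed reproduces the full trajectory.

## Irreplaceability

`selection_frequency()` repeats the annealer $R$ times with seeds
$\mathrm{seed}+1, \dots, \mathrm{seed}+R$ and scores each PU by the
fraction of runs that selected it ($\mathrm{IrSc} \in [0,1]$; $R = 1000$
in a full analysis). Scores are banded into six classes — very low
$[0, 0.2)$, low $[0.2, 0.4)$, moderate $[0.4, 0.6)$, high $[0.6, 0.8)$,
very high $[0.8, 1)$, and completely irreplaceable at exactly 1. The bands
are half-open by design so they partition $[0,1]$, and 1.0 is its own
class: a PU selected in every one of $R$ independent runs is qualitatively
different from one selected in 99%. For counting "how many wetlands a
target needs" we use IrSc $\ge 0.6$ (the high band and above).

## Target sweep and the cost-effectiveness knee

`sweep_targets()` repeats the pooled-data analysis at targets
$0.1, 0.2, \dots, 1.0$ and reports the number of PUs at IrSc $\ge 0.6$
per target together with the percent marginal increase
$100\,(n_{k+1}-n_k)/n_k$, rounded to the nearest integer percent. The knee
of this curve — the last target before the marginal cost explodes — is the
natural choice of operating target; at 100% every PU holding a single
individual becomes mandatory, which is why the final increment is always
dramatic.

## Phases and functional classification

Years are classified from total annual flow with type-7 quantiles:
*dry* strictly below the 25th percentile, *wet* strictly above the 75th,
*normal* otherwise (`classify_years()`). Strict inequalities mean a
constant flow series has no extreme years rather than arbitrary ones.

`annual_prioritisation()` runs an independent selection-frequency analysis
per year; each year reuses the same seed sequence, making years with
identical counts provably identical in output. Per-PU IrSc is then
averaged over the dry years and over the wet years, and
`functional_classification()` assigns each PU one of four roles at a
threshold of 0.6:

| dry mean ≥ 0.6 | wet mean ≥ 0.6 | role |
|---|---|---|
| yes | no | refuge |
| no | yes | breeding |
| yes | yes | both |
| no | no | neither |

Averaging per-year scores is one of two defensible readings of "IrSc under
dry years"; the alternative — re-running the prioritisation on counts
pooled within a phase — weights abundant years more heavily and is
available by pooling the counts before `selection_frequency()`, but the
phase-mean is the default throughout.

`type_irreplaceability()` sums IrSc within each wetland type (estuarine,
lacustrine, palustrine, riverine, reservoir), divides by the type's total
area — otherwise the vast floodplain types dominate trivially — and
normalises to proportions. The dry/wet contrast feeds a Pearson
chi-squared test (`pearson_chisq()`); its input is the area-corrected
score table rescaled to each phase's total summed IrSc, not an integer
contingency table, so the test is a procedural contrast rather than a
count-based inference and is documented as such.

## Driver analysis

Annual variation is regressed on water availability with BIC-approximate
Bayesian model averaging (`bma_average()`): all $2^k$ predictor subsets
are fitted by maximum likelihood, each model is weighted by
$\exp\{-(\mathrm{BIC}_m - \mathrm{BIC}_{\min})/2\}$, and models whose
posterior odds against the best exceed 20 (Occam's window) are discarded
before renormalising. The parameter count in BIC includes the error
variance for Gaussian models. Reported per predictor: the posterior
inclusion probability $pp_j$ (summed weight of models containing $j$),
the unconditional model-averaged coefficient (zero when absent), its sd by
the law of total variance, and the conditional-on-inclusion mean. Fit is
summarised by Efron's pseudo-$R^2$, the squared correlation between
observed and model-averaged fitted values.

Predictors (log flow, year, regional rainfall, climate index) are
standardised (mean 0, sd 1, $n-1$ denominator) before modelling — with
standardised predictors every Gaussian submodel's intercept equals
$\bar y$, so the averaged intercept is exactly the mean response. A
variance-inflation-factor screen precedes the enumeration: predictors are
dropped iteratively, worst first, while any $\mathrm{VIF} \ge 5$ remains.

Two responses are modelled: the annual number of required PUs (Gaussian
errors), and each PU's yearly *selection count* (IrSc $\times R$, Poisson
errors) against log flow. IrSc itself is a proportion and has no Poisson
likelihood; the selection count out of $R$ runs is the integer it rounds,
and slope coefficients are unchanged by the constant $R$ offset. Per-PU
models are restricted to PUs with nonzero IrSc in at least five years —
rarely-selected PUs carry no information about flow dependence.

## The synthetic boom-bust generator

There is no public mechanistic model of waterbird abundance in this kind
of basin, so the generator is a deliberately simple stand-in whose
obligations are statistical: it must produce flow-driven booms and busts,
a designed refuge/breeding structure that the pipeline should recover, and
overdispersed counts.

* **Flow**: $\log F_t$ is AR(1) around $\mu = 9$ with innovation sd
  $\sigma = 0.8$, persistence $\phi = 0.3$ and a coupling of $0.4$ to a
  standardized AR(1) climate index ($\phi_{soi} = 0.5$). These values give
  multi-year wet and dry spells on a 30-year horizon without the series
  wandering off its mean. Regional log rainfall correlates with
  standardized log flow at region-specific strengths (0.7 down to 0.2),
  mimicking the decay of hydrological coupling with distance from the
  basin.
* **Species totals**: $\lambda_{st} = N_s \exp(\gamma_s z_t)$, with $z_t$
  standardized log flow, baselines $N_s$ log-spaced over 200–20,000 (few
  abundant species, many rare) and boom elasticities $\gamma_s$ evenly
  spaced over 0.3–2.0, shuffled against the baselines. With these defaults
  the default 30-year run has a coefficient of variation of total counts
  near 0.9 and a roughly 40–60-fold spread between the poorest and richest
  year, matching the order of variability seen in long aerial-survey
  records of such basins.
* **Spatial allocation**: PU $i$ receives share
  $w_{it} \propto r_i + f_i \max(z_t, 0)$ — a refuge weight always active
  and a flood weight active only in wet-signed years. Designated refugia
  get $(r, f) = (1, 0.02)$, breeding PUs $(0.02, 20)$, dual-role PUs
  $(1, 20)$, background PUs $(0.05, 0.05)$: a 50:1 within-PU contrast, and
  a flood gain of 20 so floodplain capacity dwarfs refuge capacity during
  booms (birds leave the refuges when the floodplains fill). Wetland types
  are linked to role — refugia are lakes, river reaches and impoundments;
  breeding PUs are predominantly palustrine — so the type contrast has
  ecological signal.
* **Counts**: negative binomial around $\lambda_{st} w_{it}$ with
  dispersion $k = 5$; aerial survey counts are strongly overdispersed and
  a Poisson generator would understate the noise the solver must tolerate.
* **Ground truth**: roles are recorded together with the weight cutoffs
  that define them, so recovery tests have an unambiguous truth table, and
  each year's dry/normal/wet phase is stored alongside.

What the generator does *not* emulate: species' differential habitat
preferences (all species share the same PU shares within a year), survey
detection error, spatial autocorrelation among neighbouring PUs, lagged
responses to flooding, and movement between basins. Passing the recovery
tests therefore shows that the pipeline recovers a strong designed signal
through all of its stages — not that it would recover ecology from noisy
field data; with real data the printed *procedure* is identical but the
effect sizes are far smaller. One consequence of the shared-share design
is that the annual number of PUs required is nearly constant across years
in simulation, so the Gaussian driver model finds little structure there;
the per-PU flow models, by contrast, show the designed signs (refugia
negative, breeding positive... with most background PUs tracking the
refuge pool negatively).

## Problem sizes used in the shipped analyses

The `analysis/` scripts and the acceptance script run: the demo scenario
(12 species, 60 PUs, 30 years) with 50–100 annealing runs per
selection-frequency estimate at 5,000 iterations each; the recovery
scenario (50 PUs, strong contrast) with $R = 200$; 50 random 12-PU
oracle-comparison instances at 20,000 iterations; and 100-replicate BMA
calibration experiments at $n = 200$. These sizes keep a full rerun of
every analysis in a few minutes on one core while leaving every
statistical conclusion comfortably away from its threshold. A full-scale
analysis of a real basin (1,316 PUs, 52 species, $R = 1000$,
$10^5$ iterations) uses exactly the same entry points with larger
configuration values.

## Known limitations

* `exact_minset()` enumerates subsets; beyond ~20 nonzero PUs it refuses
  rather than silently taking hours.
* The chi-squared contrast on area-corrected scores inherits the original
  procedure's caveat: its inputs are not counts and the p-value should be
  read as a descriptive contrast.
* Marxan's boundary-length (spatial clumping) objective, locked-in/out PU
  status, and zoning are out of scope; the `status` column of pu files is
  read and ignored.
* BMA enumerates at most 20 predictors; the leaps-and-bounds shortcut used
  by larger analyses is unnecessary at this scale and is not implemented.
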