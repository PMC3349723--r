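---
title: "Model and methods behind hiasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind hiasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiasim)
```

`hiasim` projects the population-health consequences of a change in a
single risk factor through the causal chain risk-factor exposure →
disease incidence → prevalence → disease-related mortality → overall
population health. This vignette documents the model, its assumptions,
the tunable parameters, and the numerical and design choices made where
the design was genuinely open.

## Population and time

The population is closed (no migration), stratified by sex and single
year of age, and evolves in 1-year steps. Input tables must cover ages
0–95; internally every table lives on a 0–105 grid, with values above
the last supplied age held constant at the age-95 value so that each
cohort can be followed to the terminal age 105. At age 105 the life
table is closed: survivors die at exact age 105 and contribute no
person-years beyond it. Consequently, with zero mortality below 105, a
newborn's life expectancy is exactly 105 years. Each simulation year a
new birth cohort enters at age 0 with a user-specified size and sex
ratio.

## Partial micro-simulation

The engine is Markov-type: the next state depends only on current age,
sex, risk-factor status and health status. It splits, purely for
computational convenience, into:

1. **A stochastic micro part** (`simulate_biographies()`): individual
   risk-factor trajectories per cohort and sex. A categorical factor has
   up to ten classes; a duration-dependent factor designates one class
   whose relative risks depend on whole years spent in it (clock capped
   at `duration_max`, default 20; the cap is a free knob); a continuous
   factor is normal or log-normal with age- and sex-specific mean and
   standard deviation. For continuous exposures no transition law is
   specified by the inputs, so the engine uses **rank preservation**: an
   individual's quantile rank is drawn once at entry and re-evaluated
   against each age's distribution. This is a modelling assumption, not
   an estimate.
2. **A deterministic macro part** (`build_cohort_lifetable()`): for every
   distinct trajectory, the joint disease-state occupancy of each disease
   cluster and the survival probability are evolved annually. Identical
   trajectories are merged losslessly with summed weights, so only
   occupied states are ever computed. Micro and macro give the same
   expectation; the Monte-Carlo error of all results scales as
   n^(−1/2) in `n_biographies`.

One RNG stream per (cohort, sex) is derived from the master seed by a
fixed integer hash. Scenario runs therefore use common random numbers:
a null intervention reproduces the reference bitwise, and scenario
differences are free of between-scenario sampling noise at equal inputs.

## Parameter estimation

Only population-level epidemiological data are required; the estimation
module (`estimate_baselines()`) back-calculates what the simulation
needs.

* **Expected relative risk.** For categorical factors,
  E[RR](a,s) = Σ_c p_c(a,s) RR_c; the duration class contributes its
  RR averaged over the baseline `duration_distribution` (default: all
  mass at duration 0, i.e. everyone in the class has just entered —
  users with better information can supply the distribution). For
  continuous factors, E[RR^(X−x₀)] is computed by 96-node
  Gauss–Legendre quadrature on the distribution truncated at ±6
  standard deviations and renormalised; this matches the log-normal
  moment closed form to better than 1e-6 and keeps the expectation
  finite for log-normal exposures, whose untruncated moment diverges.
* **Baseline rates.** baseline = population rate / E[RR], applied
  identically to disease incidence and to other-cause mortality.
* **Additive mortality decomposition.** Other-cause mortality is total
  mortality minus Σ_d [prev_d·(1−cured_d)·em_d + inc_d·fatal_d]. The
  acutely-fatal term and the (1−cured) scaling follow from the disease
  model: cured cases carry zero excess mortality and acutely fatal
  incident cases die immediately. A negative cell anywhere is treated
  as an input inconsistency and reported with its (age, sex) location.
* **Class-specific disease prevalence.** Population prevalence is
  allocated over risk classes proportionally to the class RRs on
  incidence, so the prevalence-weighted mean reproduces the population
  value. This proportional-to-RR allocation is a documented choice: the
  true class split is not identified by the inputs, and
  proportional-to-RR is the stationary pattern one would expect if
  class membership were stable over life. Within a cluster, joint
  disease states at baseline are the product of the marginals
  (independence at baseline) — intermediate-disease dependence affects
  dynamics, not initialisation.
* **Net transitions** (`net_transitions()`): for each age, the annual
  transition matrix with flow only between adjacent (ordered) categories
  and, across any boundary, in one direction only, is obtained from
  cumulative prevalence differences: the net flow across boundary k is
  F_k = Σ_{j≤k} (p_j(a) − p_j(a+1)). This minimal-net-flow construction
  satisfies p(a)·T(a) = p(a+1) exactly (machine precision over long
  projections), which is the whole contract: age-specific prevalence is
  held constant over calendar time, ignoring cohort effects. A
  configuration that would require flow out of an (almost) empty class
  is reported as infeasible rather than repaired.

## Disease life tables

Diseases are chronic: excess mortality depends on age and sex, not time
since onset. Each cluster of k diseases is a 2^k joint state space;
clusters are independent. Within-year dynamics from a joint state with
incidence hazards λ_d (baseline incidence × risk-factor RR ×
intermediate-disease RRs of present diseases, evaluated from the state
at the start of the year) and disease mortality μ (Σ present
(1−cured)·em) are **competing constant hazards**: staying probability
e^(−H) with H = μ + Σλ, exit mass allocated proportionally to the
hazards, the acutely fatal fraction of incident mass dying immediately,
and **at most one incidence event per year**. The hazard formulas and
the 1-year step are fixed by the model; the within-year integration
scheme is this package's choice and is defended by a numerical oracle:
the allocation matches a 1000-substep Euler integration of the same
dynamics to better than 1e-4 for total exit hazards up to 0.5.

Other-cause mortality (times the risk-factor RR on mortality) is applied
as a separate multiplicative survival factor per year, and overall
survival multiplies it with each cluster's disease-death survival — the
total mortality hazard is additive across clusters plus other-cause
mortality, counted once. Two readings of the mortality formula are
possible: the risk-factor mortality RR could scale only the other-cause
component or the sum including excess mortality. The engine scales
**only the other-cause component**, because disease excess mortality is
already disease-specific and scaling it again would double-count the
risk factor's effect through incidence; this is the main fidelity risk
relative to other implementations of the same model family and is
deliberately pinned by tests. Remission is not modelled explicitly; the
cured fraction is implemented as a (1−cured) scaling of excess
mortality, equivalent to a zero-excess sub-population without enlarging
the state space. Intermediate-disease links must be acyclic and within a
cluster.

## Outcomes

Cohort life tables are aggregated across cohorts at a simulation year
(period, cross-sectional) or along cohorts (longitudinal). Life-table
conventions, which the measures' definitions leave open, are: deaths
receive a half-year person-year credit (a_x = 0.5); combined-sex life
expectancy weights the sexes by the newborn sex ratio; period
disease-free life expectancy uses the Sullivan construction (period
prevalence × period person-years) while the cohort variant integrates
occupancy directly (trapezoidal, consistent with a_x = 0.5). Period
rates at ages no cohort occupies yet (above 95 + t in early years)
carry the last populated age's rate forward, consistent with the input
extension rule; period life expectancy is therefore defined for every
simulated year, and exact once all ages are populated (t ≥ 10 with
newborns present).

## Scenarios

A scenario may (i) replace the initial risk-factor prevalence with a
counterfactual — a one-time, sustained intervention, applied to the
starting population at year 0 and to every entering newborn cohort —
and/or (ii) override the transition model, each restricted to a target
age window and sex set. A target window reaching the last input age
(95) also covers the internal 96–105 extension. Partial uptake is
expressed as a mixed counterfactual prevalence; there is no separate
compliance parameter. Newborn cohorts inherit the scenario's (not the
reference's) age-0 prevalence, and transition overrides apply to them
from entry. When the transition mode is `net` and a counterfactual is
applied, net transitions are estimated from the scenario's own
prevalence, so each scenario holds its own age profile constant.

A counterfactual changes exposure, not the disease burden already
accumulated at year 0: initial risk-factor states are coupled across
scenarios through a shared uniform draw, and each individual's initial
disease occupancy is taken from the class drawn under the *reference*
prevalence. Baseline rates are likewise estimated once, from the
observed inputs, never from counterfactual prevalences. Outputs at the
initial year are therefore identical across scenarios, and differences
accumulate only through the altered exposure dynamics.

## Synthetic data

No external dataset is bundled; `make_toy_dataset()` generates
internally consistent inputs. Its defaults describe a small,
plausible population: ~100 persons per year of age and sex, constant
newborn inflow, Gompertz-like other-cause mortality
(5·10⁻⁴·e^(0.065·age)), two chronic diseases with age-increasing
incidence near 1%/year and excess mortality near 2%/year, three ordered
exposure classes (prevalence 0.5/0.3/0.2) with incidence RRs up to 2 and
mortality RRs up to 1.8 — magnitudes typical of smoking- or
alcohol-related epidemiology. Total mortality is constructed as
other-cause mortality plus the attributable terms, so the additive
decomposition is exact by construction and simulated first-year
mortality closes on the input (to within the within-year interaction
terms, well under 2%). `make_closed_form_case()` emits configurations
with analytically known outputs (constant-hazard life expectancy,
single-disease occupancy 1−e^(−λt), two-cluster independence, a
stationary population) used to validate the pipeline end to end.

What the generator does *not* emulate — cohort trends in exposure,
time-varying rates, migration, dependence between diseases at baseline,
reporting error — bounds what passing tests show about real data: they
establish the engine's internal correctness and its contracts, not the
realism of any particular application's inputs.

## Problem sizes and runtime

Default test and example sizes are chosen so the whole suite runs in
minutes on one CPU: 2 sexes × ages 0–105, ≤ 3 classes, ≤ 2 diseases,
150–1,000 biographies per cohort and sex for full-population runs, and
10,000 biographies for single-cohort Monte-Carlo checks (asserted at 3
standard errors). Because the macro part is deterministic, scenario
*differences* are far less noisy than absolute levels at equal
`n_biographies`.

## Known limitations

One risk factor per run (joint factors can be encoded as combined
categories); closed population; no autonomous secular trends in rates;
no probabilistic sensitivity analysis (the package is scriptable, so a
PSA shell can be built around `run_hia()`); continuous-exposure runs
evaluate per-individual hazards and are correspondingly slower, so they
are best used with modest `n_biographies`.
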