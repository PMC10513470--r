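---
title: "Projecting oral disease burden with a multi-state population model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting oral disease burden with a multi-state population model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralproj)
```

## The model and its assumptions

`oralproj` implements a discrete-time (annual Euler) stock-and-flow
population model. The whole population is disaggregated by single year of
age (0–99 plus an open 100+ accumulator) and sex. One calendar-year update
applies, in fixed order:

1. **mortality** on start-of-year stocks: survivors are `n · (1 − q)` with
   `q(age, sex)` the life-table annual death probability;
2. **net migration**, added cell-wise and *flow-limited*: out-migration can
   never drive a cohort below zero — any shortfall is logged, never silently
   redistributed;
3. **aging with births**: every surviving cohort moves up one age, the 100+
   cohort retains its own survivors, and births
   `B = Σ_{a=15..49} f(a) · n_female(a)` (computed from start-of-year
   stocks) enter age 0, split by a male fraction of 0.512 (the conventional
   ~105:100 sex ratio at birth).

This ordering is a modelling choice — annual survey and registry data do not
identify the within-year sequence — and it is the one under which the balance
identity `total(t+1) = total(t) − deaths + births + realized migration`
holds exactly, which the tests exploit.

Three disease chains ride on this engine. Each is declared as an ordered
state list with rate-named edges (`chain_spec`), and everyone below the
chain's entry age is carried in the disease-free state, so "individuals
reaching the entry age transition directly into the disease-free state" is a
consequence of the data layout rather than a special case:

| chain | states | entry age | edges |
|---|---|---|---|
| caries | no / untreated / treated caries | 16 | incidence, treatment uptake, treatment cessation (backward) |
| pocketing | none, 4–<6, 6–<9, ≥9 mm | 16 | forward-only severity progression |
| loss of attachment | none, 4–<6, 6–<9, ≥9 mm | 55 | forward-only severity progression |

Transition flows are *simultaneous* from start-of-year stocks
(`flow = rate × stock` per edge), the stock-and-flow convention; states are
not drained sequentially. If the combined outflow fraction from a state ever
exceeds 1, that state's rates are rescaled proportionally for the year and a
warning raised. Mortality is state-independent within an age/sex cell, and
all transition rates are constant across age and over time — strong
assumptions, which is precisely why the sensitivity analysis varies every
one of them.

Net migration is reported for the population, not by health state, so its
allocation across states within a cohort is genuinely open. The default
allocates proportionally to current state occupancy (migrants resemble the
residents of their cohort); a `disease_free_only` strategy is provided for
the alternative reading. Under the proportional default the chain's
state-marginals match the demography-only projection to machine precision,
a conservation contract the acceptance tests check over 30-year runs.

## Parameters

| parameter | units | default / source |
|---|---|---|
| `q(age, sex)` | deaths per person-year, [0, 1] | life table input |
| `f(age)` | births per woman-year, ages 15–49 | fertility schedule input |
| `male_fraction` | fraction of births male | 0.512 |
| `m(age, sex)` | net migrants per year (may be < 0) | migration profile input |
| migration `scaler` | dimensionless ≥ 0 | 1; optionally calibrated |
| 9 chain rates | fraction of source stock per year, [0, 1] | calibrated |

Rates may differ by sex (the model is fitted separately by sex when the
targets support it); a plain named vector ties the sexes, which is also how
the synthetic truth is defined.

## Calibration

A single cross-sectional survey cannot identify per-year transition rates,
so the standard device is used: banded survey prevalence, held at its
reference-year values, multiplied by the projected population gives a yearly
series of state counts, and the rates are chosen to reproduce it. Choices the
data do not dictate, and how they were fixed:

* **Objective** — weighted sum of squared *relative* errors,
  `Σ w ((proj − target)/max(target, 1))²`, with weights normalized to mean 1.
  Relative errors keep states of very different sizes (e.g. severe pocketing
  vs. no-pocketing) commensurate; the 1-person floor keeps empty target
  cells finite. Calibration is to **counts**, not proportions (a switch at
  the target-construction level lets users fit proportions instead, by
  normalizing their targets).
* **Optimizer** — Nelder–Mead (`stats::optim`), run in a logit-transformed
  coordinate system so box bounds `[0, 1]` are respected exactly without
  penalty terms; one-dimensional problems use Brent. Five multi-starts from
  fixed seeds (box midpoint plus four interior draws) guard against the mild
  non-smoothness the flow caps can induce; starts stop early once a misfit
  below 1e−12 is found. Degenerate bounds pin a parameter. Everything is
  deterministic given the settings.
* **Calibration window** — targets are built from the reference year forward
  for a configurable window (the synthetic default is 11 years, emulating a
  2009 survey calibrated through 2020), after which the model runs freely.
* **Migration** — a single global scaler on an exogenous age profile can be
  added to the free parameters; free per-age migration would be hopelessly
  underdetermined by banded targets.

The treated→untreated "cessation" flow is a direct backward edge (treated
fillings failing back into active decay), not a return through the no-caries
state: recovery to a caries-free dentition is not how restorative history
works, and the chain structure encodes that.

## The synthetic-data generator

`generate_study()` stands in for the survey and national-statistics inputs,
with known ground truth so the pipeline is validated by *parameter
recovery*:

* Gompertz–Makeham mortality `q(a) = min(1, floor + a·e^{b·age})` per sex,
  with a female advantage (defaults give a period life expectancy near 80);
* a flat-with-peak fertility schedule, total fertility ≈ 1.6 (sub-replacement,
  UK-like);
* a piecewise-linear age pyramid with a working-age bulge, a seeded 2%
  log-normal ripple, and rising female share at old ages, scaled to 1 million
  persons — large enough that stochastic rounding is irrelevant, small enough
  that a full calibration runs in seconds;
* net immigration of 0.3% of the population per year, concentrated at ages
  18–45;
* true rates: caries 0.04 / 0.30 / 0.05, pocketing 0.07 / 0.02 / 0.01, LOA
  0.08 / 0.03 / 0.01 per year — fixture choices in the plausible range, not
  estimates.

Each chain is forward-simulated from an all-disease-free population for a
60-year burn-in, so reference-year occupancy is an *emergent equilibrium* of
the true rates rather than an imposed pattern; prevalence is then tabulated
in decade-style survey bands (16–24, 25–34, …, 75+), which deliberately
discards the single-age detail and forces the band-to-age step-function
logic to be exercised. The calibration targets are the banded counts of a
forward run restarted from the banded-prevalence initialization — the same
information a real analyst would have — which makes the true rates the exact
minimizer (misfit 0) and parameter recovery a sharp test: noise-free
recovery is within 2% relative for every rate of every chain, and within
10% under 5% multiplicative target noise.

What the generator does *not* emulate — survey design effects (clustering,
weighting, nonresponse), secular trends in prevalence, differential
mortality by disease state, tooth-level detail, and real migration age
profiles. Passing tests therefore demonstrate that the machinery is correct
and the rates identifiable under the model's own assumptions, not that the
model is a faithful description of any real population.

## Sensitivity analysis

All twelve parameters (fertility, net migration and mortality as scalar
multipliers on their whole age schedules, plus the nine chain rates) are
drawn independently and uniformly on `[base·(1−v), base·(1+v)]` with
`v = 0.5`, rates clipped to `[0, 1]`; the full model is re-run per draw.
Varying a schedule by a single multiplier, not per-age draws, matches the
"±50% on the parameter" design and keeps the age shape fixed. The printed
"95% interval" is the ensemble mean with empirical 2.5th/97.5th percentiles
(linear-interpolation, type-7 definition); ensemble minima and maxima are
emitted alongside, since reasonable readers differ on which an "interval at
95%" means. An optional pairwise (two-parameter grid) mode covers the
classical two-way design. The reference ensemble size is 500 runs; tests and
the acceptance script use 50-run ensembles over a 20-year horizon, which
already pin down the contract being tested (ordering, baseline coverage,
zero width at `v = 0`, seed-exact reproducibility).

## Reporting arithmetic

Report tables aggregate to the 16–24 / 25–59 / 60+ bands, in millions to 3
decimals, with relative changes (1 decimal) and shares (2 decimals) rounded
**half-up** — `round_half_up()` exists because banker's rounding in base
`round()` reproduces published health-report tables incorrectly at exact
ties. Interval bounds on relative changes are percentiles of the *per-run*
relative changes, not changes of the percentile bounds, which would ignore
the dependence between a run's 2020 and 2050 values. A handful of published reference percentages do not
round cleanly from their own printed point estimates (they were evidently
computed from unrounded internals); the package asserts only the cells that
reproduce exactly and carries the rest as data.

## Numerical notes and degenerate inputs

* Conservation holds to ~1e−15 relative; tolerances in tests are 1e−9.
* Cohorts receiving migrants while empty place them in the disease-free
  state (the only defensible default for a 0/0 occupancy share).
* Proportional migration allocation can produce −1e−17-scale round-off;
  cells are clipped at zero below 1e−9 in magnitude.
* `n_years = 0` projections return the initial snapshot; empty target sets
  and non-tiling age bands are rejected at construction, not at use.
* Problem sizes: the test suite calibrates 6 problems (3 chains × 2 noise
  conditions) on an 11-year window and runs ensembles of 5–50 over 10–41
  years; the full suite completes in under two minutes on one core.

## Known limitations

Constant rates over age and calendar time; prevalence held at reference-year
values when building targets (so secular improvement in oral health is
outside the model); state-independent mortality; no edentulism state and no
caries–periodontitis interaction; calibration is a point estimate with
multi-start — no posterior uncertainty on the rates themselves (the ±50%
ensemble is a deliberate, wide, assumption-driven band, not a confidence
interval in the statistical sense).
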