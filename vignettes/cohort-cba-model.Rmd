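---
title: "Methods: the PPV23 cohort cost-benefit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PPV23 cohort cost-benefit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppv23cba)
```

## Scope and model structure

`ppv23cba` evaluates three strategies for single-dose PPV23 vaccination of
a closed cohort of adults aged 60+ — government-funded (free), self-paid,
and none — with a decision tree over a Markov cohort engine. The decision
tree assigns people to an arm once, at t = 0, according to the strategy's
coverage; within an arm, a five-state annual-cycle Markov model produces
expected health outcomes. The five states are `HEALTHY`, `HOSP_CAP`
(hospitalized community-acquired pneumonia), `HOSP_MENINGITIS`,
`PNEUMO_DEATH` and `ALL_CAUSE_DEATH`. Transitions depend only on the
current state; vaccine protection is applied as a constant multiplicative
reduction of the disease entry probabilities over the whole 5-year horizon,
which is taken to match the duration of vaccine-induced protection. Waning,
serotype replacement and herd effects have no functional form here: the
model deliberately holds efficacy constant within the horizon rather than
invent one.

Structural choices worth making explicit:

- **Hospital states are one-cycle tunnels.** An acute episode resolves
  within the 1-year cycle: survivors return to `HEALTHY`, the rest move to
  `PNEUMO_DEATH`. No episode lasts more than one cycle.
- **Case fatality is derived, not an input.** The inputs are
  population-level incidence and mortality rates per 100,000 person-years;
  the per-episode death probability is their ratio (0.2953 for CAP,
  0.381 for meningitis at base case), which presumes all fatal cases occur
  among the hospitalized — consistent with hospital-based mortality
  sources. `build_transition_matrix()` refuses a mortality rate exceeding
  its incidence rate.
- **Competing risks within a cycle** (CAP, meningitis, background death)
  are applied as independent exit probabilities from `HEALTHY`, residual
  mass staying healthy. Their sum is ≈ 7 × 10⁻³ at base case, so
  normalization subtleties are far below every tolerance used; they are
  documented rather than corrected.
- **No half-cycle correction.** With costs booked at t = 0, benefits
  treated as annual flows, and a 5-cycle horizon, the uncorrected
  first-order accounting is the convention this base case encodes.

## Rates, probabilities and numerical conventions

Disease rates are quoted per 100,000 person-years (background mortality per
1,000). `per_capita_rate()` converts them by direct division; the
competing-risks form 1 − exp(−r) is available via
`settings$rate_conversion = "exponential"`. At the magnitudes involved
(≤ 6.25 per 1,000) the two differ by under 0.02%, and direct scaling
reproduces the base-case expected case counts exactly, so it is the
default.

Cohort arithmetic is expected-value matrix propagation
(`occupancy[c+1] = occupancy[c] %*% M`), never sampling, so results are
deterministic to machine precision. Transition matrices must be
row-stochastic within 10⁻¹²; traces conserve persons within 10⁻⁶ relative
and death-state occupancy is non-decreasing. The test suite checks the
engine against an independent oracle that enumerates every explicit state
path over the 5-cycle horizon.

## Economic accounting

All internal accounting is in CNY; conversion to USD happens only at
reporting time (single fixed rate, no inflation adjustment), to avoid
compounding rounding. Reported tables round money to 2 decimals and ratios
to 3 at serialization only.

**Costs** are incurred at t = 0, undiscounted: a single-dose campaign at
programme start. Components per dose: vaccine price (166 CNY), cold chain
and consumables (32 CNY), delivery service, plus expected severe
adverse-event treatment (0.53 per 100,000 doses at 7,155.21 CNY). Wastage
enters procurement as a `doses × (1 + wastage)` multiplier.

**Benefits** are pneumococcal disease costs averted — hospitalization plus
caregiver income loss — as a constant annual flow over years 1..5,
discounted at r (3% base): `total = annual × Σₜ (1+r)⁻ᵗ`
(`annuity_factor()`). Deaths are not monetized, and adverse-event costs are
charged to the vaccinating strategy, never negated into a benefit. Averted
annual cases equal `doses × incidence × efficacy`, which is identical to
the first-cycle incidence difference between equal-sized unvaccinated and
vaccinated cohorts; the tests assert the equivalence against the Markov
engine.

Under this convention costs are a per-dose constant and benefits a per-dose
constant, so the BCR is invariant to coverage: the free and self-paid arms
share one BCR, and any published table showing materially different BCRs
across arms is using arm-specific unit assumptions that cannot be derived
from these inputs. The package reports its own, internally consistent,
values. The ICER between strategies is likewise reported as computed.

## Calibration parameters

Four quantities the base case needs are not standard published inputs and
are shipped as explicit, overridable calibration values:

- `cny_per_usd = 7.17` — implied by the base case's own CNY/USD pair for
  the low pneumonia treatment cost (8,500 CNY ≡ USD 1,185.5).
- `service_per_dose = 10.14` CNY — back-calculated so free-arm service
  delivery totals USD 0.26 M over 183,806 doses.
- `caregiver_days = 10` days per hospitalization episode, turning the
  120 CNY/day caregiver income loss into a per-episode amount; 10 days is
  a realistic length of stay for hospitalized CAP in this age group and
  makes the free-arm benefit consistent with the encoded base case to
  within 0.5%.
- `wastage = 0` in the shipped base case — the procurement figure the base
  case encodes excludes wastage — while the published plausible range
  (1.3–1.68%) is preserved on the entry for sensitivity runs. Validation
  flags the base-outside-range anomaly as a warning, not an error.

The serotype-coverage multiplier (96.6%) ships but defaults to off
(`settings$serotype_switch`): base-case expected case counts correspond to
efficacy unscaled by serotype coverage. Switching it on multiplies
effective efficacy in the vaccinated arm for scenario analysis.

## Sensitivity analysis

`one_way()` re-runs the full pipeline at a parameter's low and high bound —
never linear interpolation — so the near-insensitivity of the meningitis
parameters (BCR spread ≤ 0.002) is an emergent result. Degenerate ranges
(`low == high`) return a skip signal rather than an error. `tornado()`
sorts entries by spread, descending, ties broken alphabetically by
parameter path for deterministic output.

The default tornado parameter list (`key_parameters()`) is the set the
headline analysis varies: efficacy and hospitalization cost for both
diseases plus the discount rate. `parameters = "all"` additionally varies
the incidence and coverage ranges; note that CAP incidence (25–45 per
100,000) then produces the largest BCR spread of all, ahead of efficacy —
worth knowing before treating the default ranking as complete. Coverage
has zero BCR spread by the invariance noted above.

Raising the discount rate from 3% to 5% lowers the BCR by ≈ 5.5% under
this package's convention (benefits discounted, costs at t = 0). Published
figures of ≈ 14.5% for the same move are not reproducible under any
discounting convention we tried (discounting both sides leaves the BCR
even less sensitive); the package reports its computed value.

## Synthetic scenarios

`sample_parameter_sets()` draws every ranged parameter independently and
uniformly within its plausible range — the ranges are ranges, not
distributions, and uniform sampling is the honest default; a
base-anchored jitter mode exists for perturbation studies. Draws are fixed
bit-for-bit by the spec's seed and leave the caller's RNG stream
untouched. `stress_cases()` adds labeled deterministic edges (zero/full
efficacy, zero incidence, r = 0, coverage 0/1, case fatality 1) that the
pipeline must survive with exactly-zero or boundary outcomes.

What generated scenarios emulate is parameter uncertainty only: every set
is a coherent single-cohort, constant-rate world. Passing tests on them
demonstrates the arithmetic and its invariants, not the realism of the
epidemiology — no age structure within the 60+ cohort, no transmission
dynamics, no time-varying incidence or costs.

## Problem sizes and defaults

The shipped evaluation uses the full cohort (1,367,900 people, 5 annual
cycles) — small enough that every pipeline stage is effectively instant.
Property tests run on batches of 10–25 sampled parameter sets and a
1,000-draw range check; the path-enumeration oracle covers all
5¹ + … + 5⁵ state paths.

## Known limitations

- Single homogeneous cohort; no age-stratified rates within 60+.
- Static model: no herd immunity, serotype replacement or waning.
- Benefit is treatment cost averted only — no QALYs/DALYs, no value of
  statistical life, so mortality benefits are invisible in NB/BCR.
- Single fixed exchange rate; no price-year adjustment.
- The published self-paid benefit and ICER this evaluation is usually
  compared against are not derivable from the shipped inputs (see the
  coverage-invariance note); the package's outputs for that arm follow
  linear per-dose scaling and are labelled as such in run manifests.
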