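---
title: "Methods: a Markov cohort cost-utility model of TKA, UKA and HTO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-utility model of TKA, UKA and HTO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneecua)
```

## The decision problem

Young adults (modelled here as a 45-year-old cohort) with isolated medial
compartment knee osteoarthritis who fail conservative treatment face three
surgical options in broad clinical equipoise: total knee arthroplasty (TKA),
unicompartmental knee arthroplasty (UKA), and medial opening wedge high
tibial osteotomy (HTO). The three differ in upfront cost, in the utility of
the well postoperative state, in how often they fail, and — distinctively —
in *how* they fail: failures with postoperative joint instability require a
varus-valgus constrained (VVC) revision prosthesis, which is substantially
more expensive and leaves patients at a lower utility than a standard
revision. `kneecua` implements a discrete-time Markov cohort model of this
choice from a public-payer perspective and the full economic toolkit around
it: league tables with dominance classification, ICERs, net monetary
benefit, probabilistic sensitivity analysis (PSA) with acceptability curves,
deterministic sensitivity analysis (DSA), and sex-specific mortality
scenarios.

## Model structure

Time advances in one-month cycles from age 45 (cycle 0) to age 90 (cycle
540), after which accrual simply stops — the cohort is not forced to
extinction. States and transitions per strategy:

* `WELL_PRIMARY`: well after the index surgery. Each month a strategy-
  specific failure probability applies, split by the conditional instability
  fraction into the two failure routes.
* Failure states are **one-cycle transient surgery states**: the revision
  cost (hospital cost plus surgeon fee) is charged once on entry, the
  failure utility applies for that single month, and survivors move on. The
  waiting time to revision is not modelled separately; one cycle is the
  simplest structure consistent with a failure → revision → recovery
  sequence.
* Non-instability failure of TKA or UKA → revision with a primary prosthesis
  → `WELL_POST_REV1`. A further failure from there (at the primary-TKA
  failure rate — no separate post-revision rate is published) is revised
  with a VVC prosthesis regardless of mode → `WELL_POST_VVC`, which has no
  further surgical transitions: beyond a second revision only death
  competes.
* Instability failure anywhere → VVC revision → `WELL_POST_VVC` directly.
  The alternative reading, that a *first* instability failure is revised
  conventionally and only recurrent instability earns the VVC implant, is
  not supported by the published costs/utilities (they price exactly one
  constrained tier), so a single instability event triggers the VVC pathway.
* HTO failure without instability converts to TKA (charged as a primary TKA
  plus the hardware-removal surgeon fee) → `WELL_TKA_AFTER_HTO`, which then
  follows the primary-TKA pathway. HTO failure with instability is revised
  with a VVC implant (VVC hospital cost plus the hardware-removal fee —
  hardware must come out regardless of the implant chosen).
* Death competes from every state at the age-specific background rate,
  applied before event probabilities; event probabilities are scaled by the
  survival complement so every row of the transition matrix is stochastic.

Perioperative death is represented by an explicit parameter applied at model
entry, with default 0: the failure probabilities come from registry
composite outcomes that already fold in perioperative events, and no
separate perioperative mortality is published.

## Inputs

The bundled `table1.yaml` carries the base case: monthly failure
probabilities (TKA 29.559e-4, UKA 8.1627e-4, HTO 33.158e-4), conditional
instability fractions (0.124, 0.062, 0.095), state utilities (well after
TKA/UKA/HTO 0.840/0.870/0.835; post-first-revision 0.772; TKA-after-HTO
0.804; post-VVC 0.740; failure-month utilities 0.50-0.69), hospital costs
and surgeon fees in 2023 CAD, a 1.5% annual discount rate, and a
willingness to pay of $4,166.67 per quality-adjusted life month (QALM) —
$50,000 per QALY. The instability fractions are interpreted as the
conditional probability that a failure involves instability (their
plausible ranges, about 0.05-0.15, are far larger than the monthly failure
probabilities, so they cannot be absolute monthly probabilities). Inputs
lacking a published SD get 20% of the mean; inputs lacking a usable range
get the central 95% interval of their assigned distribution.

## Mortality

Background mortality is a step function of age: an annual probability
looked up for the current year of age, converted to a monthly probability
by `1 - (1 - q)^(1/12)`, and updated on each birthday — matching an annual
dynamic update of life-table mortality. Whether one should instead
interpolate within years is not determined by the published description;
annual stepping was chosen as the stated update granularity.

National life tables cannot be redistributed with the package, so the
`synthetic_data` module generates Gompertz–Makeham tables,
`q(age) = min(1, (A + B·e^(c·age)) · m)`, with `A = 5e-4`, `c = 0.095`
(typical adult-mortality values) and `B` calibrated by root-finding so that
remaining life expectancy at 45 equals published Canadian values: 37.8
years for the general population, 36.0 for males, 39.6 for females. These
targets were fixed before any model output was inspected. The synthetic
tables reproduce the *level* and exponential *shape* of Canadian adult
mortality but not year-to-year irregularities, cause structure, or cohort
improvements — so agreement of downstream results certifies the model
machinery, not the exact national mortality experience.

## Accrual conventions

* **Discounting** uses the continuous-equivalent monthly factor
  `(1.015)^(-t/12)` rather than annual steps, consistent with monthly
  cycles.
* **Within-cycle correction**: QALMs accrue by the trapezoidal (life-table)
  method, `½(occ_t + occ_{t+1})` per cycle, discounted at mid-cycle
  `d(t + ½)`. The corrected total provably lies between the start- and
  end-of-cycle accruals (a tested invariant).
* **One-time costs are event-dated, not half-cycle corrected**: each
  arrival into a surgery state at cycle *t* is charged that state's entry
  cost at `d(t)`; the index surgery is charged undiscounted at cycle 0.
  Half-cycle correction targets state-membership accruals, not dated
  events.

## Validation oracle

`microsim_oracle()` is an individual-level simulation of the identical
transition rules and accrual conventions. The cohort engine computes the
expectation of that stochastic process, so the two must agree within
Monte-Carlo error; the suite checks agreement within 3 standard errors at
n = 200,000 for the base case (and at smaller n on an event-rich test
fixture with failure probabilities inflated 50-fold), plus the closed-form
geometric-series limit under constant mortality.

## Uncertainty analysis

**PSA** draws utilities and probability-type parameters from beta
distributions and costs/fees from gamma distributions, method-of-moments
parameterised — distribution families are published only for utilities and
costs; beta is the natural bounded choice for probabilities, and a config
freeze switch can hold them fixed instead. One shared draw is applied to
all three strategies per iteration (paired sampling; incremental
comparisons would otherwise be needlessly noisy), with 3,000 iterations by
default and no correlation structure (none is published). The acceptability
curve is evaluated on a default WTP grid of 0–10,000 CAD/QALM in steps of
100 with 500 and 4,166.67 inserted.

**DSA** scans each parameter over its plausible range with all others at
their means (21 grid points by default), orders parameters by tornado
spread of INMB(UKA, TKA), refines break-even points by bisection
(`uniroot`, tolerance 1e-4), and maps two-parameter interactions onto an
optimal-strategy grid. Because every utility's published plausible range is
the uninformative 0–1, utility DSA ranges default to the central 95%
interval of the utility's beta distribution — the published break-even
value for the UKA well-state utility (0.823) lies comfortably inside that
interval, so the convention spans the decision-relevant region.

**League table**: absolute dominance (no more costly and no less
effective, one inequality strict) is always flagged; extended dominance
(ICER non-monotonicity along the frontier) is implemented but off by
default, since with three strategies and one absolute domination it cannot
trigger in the base case. ICERs are reported between successive undominated
strategies, with the quadrant flagged for sign-ambiguous comparisons.

## Problem sizes

Default analyses are desk-scale by construction: a single cohort run is a
540-step recursion over an 11-state occupancy vector (~4 ms), a full
3,000-iteration PSA of all three strategies completes in well under a
minute, and the 200,000-patient oracle run takes a few seconds. The test
suite uses the inflated-failure fixture and smaller simulation sizes where
the property being checked does not need full scale.

## Known limitations

* The synthetic life tables are calibrated stand-ins; results that depend
  on the fine structure of national mortality (QALM totals most directly)
  carry a percent-level uncertainty from that source alone.
* Post-revision failure rates reuse the primary-TKA rates; no separate
  published rate exists.
* Septic failure, hinged prostheses, bilateral disease, comorbidity strata
  and patient-level heterogeneity are out of scope; the cohort is
  homogeneous by construction.
* Costs are 2023 CAD as given, with no inflation or currency adjustment.

## A note on internal consistency of the published base case

With the published monthly failure probabilities, a large share of the TKA
cohort is revised at least once over 45 years
(`1 - exp(-29.559e-4 × t)` exceeds 70% by t ≈ 410 months), which at the
published revision costs adds several thousand discounted dollars per
patient to every arm — yet the published lifetime costs are
indistinguishable from the index surgery costs alone. Both cannot hold
under any accrual convention. This package accrues revision costs as the
model structure dictates; the consequences (lifetime cost ordering, the
sign of the UKA-vs-TKA ICER, cost-driven probabilities at very low WTP)
are reported as computed, and the acceptance checks against the published
cost figures are allowed to fail rather than suppressing the accrual.
Quantities dominated by effectiveness at realistic WTP — NMB ordering, the
probability UKA is optimal, the UKA utility break-even — are robust to
this discrepancy.
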