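---
title: "Modelling the cost-effectiveness of fluoride varnish in preschool children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of fluoride varnish in preschool children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvcea)
```

## The decision problem

Professional fluoride varnish (FV) is widely recommended for caries
prevention in preschool children, but its effect is modest (pooled relative
risk 0.88 for developing at least one cavity) while its application is
costly when performed by dentists at private-clinic rates. This package
models whether adding semiannual FV to standard preventive care is good
value for money for a Brazilian supplemental-health payer, with all costs in
2022 Reais.

## Model structure and conventions

The cohort model has three health states — *no cavity*, *cavity*, *previous
cavity* — over eight 6-month cycles (ages 2 to 6, covering the primary
dentition). Every child enters caries-free, caries risk is constant over
time, there is no mortality or dropout state, and the unit of analysis is
the child, assumed to carry at most one cavitated lesion at a time.

Three conventions deserve emphasis, because different placements of the
same probabilities give different cohort curves:

* **Treatment resolves within the cycle.** A child in the cavity state at a
  cycle's start is allocated to glass ionomer (0.873), Hall technique
  (0.004) or extraction (the complement, 0.123) during that cycle. Success
  (0.63, 0.98, and 1 respectively) moves the child to *previous cavity* by
  cycle end; failure returns the child to *cavity*. The cavity row of the
  transition matrix is therefore (0, q·f, q·s + q_ext), and the self-loop on
  the cavity state is exactly the expected failure mass. Extraction has no
  failure branch: it always resolves the cavity. This timing reproduces the
  published end-of-simulation occupancies (57/16/28% standard care,
  61/13/26% with FV).
* **No half-cycle correction.** Occupancy is reported at integer cycle
  boundaries and each cycle's rewards are discounted with the end-of-cycle
  factor `(1.05)^(-t/2)`. The published occupancies are matched without a
  half-cycle adjustment, so none is applied.
* **The FV effect is a multiplier on exactly four probabilities** — the
  no-cavity→cavity progression, both restoration failure probabilities, and
  the previous-cavity→cavity relapse — never on the treatment mix. The
  packaged parameter table stores the resulting products (0.0604824, 0.3256,
  0.0176, 0.2464) and the loader verifies they equal the products of the
  standard-care values and the relative risk.

## Parameters

`load_parameter_table()` returns the packaged registry: per-record id, role
(probability / cost / relative-risk / …), arm, baseline, lower and upper
bound, and distribution family. Model constants live in the same registry:
discount rate 0.05/yr, 8 cycles of 0.5 yr, DALY disability weight 0.01/yr
while a cavitated lesion is present, and willingness-to-pay anchors of
R$40,000 per DALY (≈ 1 GDP per capita) and R$60 per cavity avoided. Users
can supply their own CSV of the same schema; validation enforces the bound
invariants, chance-node closure (`q_gic + q_hall + q_ext = 1`), the 4-year
horizon identity, and the product identity for the FV rows.

## Cost and effectiveness accrual

The published per-arm accumulated totals cannot be derived from the unit
costs under any simple reward placement — the defining accrual tree was not
published — so the package implements an explicit, configurable scheme and
treats those totals only as arithmetic inputs to the incremental identities.
The default scheme accrues, per cycle: the routine-visit cost (R$118.50,
identical in all three states; occupancy taken at cycle end by default,
`accrual = "cycle_start"` is available), the expected treatment costs
(R$179.50 glass ionomer, R$254.50 Hall, R$172.50 extraction) attributed
from start-of-cycle cavity occupancy, and on the FV arm the R$78.00
application every cycle regardless of state, since the visits are
semiannual by design. Under this scheme the base-case incremental cost is
R$540.75 per child and the deterministic ICERs are ≈ R$13,078 per child
kept cavity-free and ≈ R$815,972 per DALY avoided; these are the package's
own numbers, with the qualitative conclusion (FV is not cost-effective at
conventional thresholds) unchanged.

Effectiveness is explicit configuration rather than a hidden convention,
because "cavities avoided" admits several operationalisations:

* `ever_cavity_avoided` (default for the cavity outcome): the probability of
  never developing a cavity, `(1 - p)^8`. Because the no-cavity state has no
  inflow, this is a closed form, and the between-arm difference (0.0413) is
  the headline "4 in 100 children" quantity. It is a terminal probability,
  so it is not discounted.
* `cavity_free_time`: discounted years in the no-cavity state.
* `expected_cavities`: discounted expected entries into the cavity state
  from no-cavity or previous-cavity. Restoration failures keep the child in
  the cavity state and are deliberately not counted as new cavities.
* `daly` (default for the DALY outcome): discounted cavity-state occupancy ×
  0.5 yr × 0.01. DALYs are a harm, so the incremental effect is reported as
  DALYs avoided (comparator minus intervention).

Outcomes are discounted with the same factor as costs.

## Sensitivity analyses

**One-way (tornado).** Each underlying variable is pinned at its lower and
upper bound with everything else at baseline, and the full two-arm analysis
is recomputed. The varied set is the standard-care probabilities (95% CIs),
the relative risk (0.81–0.95) and the unit costs (±20%). The FV-arm
probability rows are *formula rows*: their published bounds are exactly the
standard-arm bounds times the relative risk, so they are not varied as
independent parameters — varying the underlying variable moves both arms
coherently through the product derivation. (Varying them independently
would let the wide relapse-probability interval dominate the DALY tornado,
which contradicts the consistent finding that the FV relative risk is the
most influential parameter; `one_way_dsa()` still accepts a derived row's
id directly for scenario exploration.) With the published bounds the
relative-risk bar is the widest for both outcomes by more than a factor of
four.

**Probabilistic.** `run_psa()` samples every parameter independently:
probabilities from beta distributions fitted by method of moments to the
published mean and 95% CI (standard deviation = CI width / 3.92), costs
from gamma distributions with a 20% coefficient of variation, and the
relative risk from a lognormal whose median equals 0.88. Complements are
closed after sampling so each chance node remains a distribution; draws
that violate a node constraint (mix summing above one, derived probability
above one) are rejected and redrawn, with the count retained for audit —
rejection preserves the fitted family's shape where truncation would not.
Each iteration runs on a deterministic substream of the root seed, so runs
are byte-identical under the same seed and any single iteration is
reproducible in isolation. `sd_scale = 0` collapses every distribution to
its point mass and must reproduce the deterministic base case exactly,
which the tests assert. The default 1000 iterations keep the Monte-Carlo
error on the acceptance probability below ±1.6 percentage points.

**Acceptability.** `ceac()` reports, on a willingness-to-pay grid (default
0 to twice the deterministic ICER in 200 steps), the fraction of iterations
with non-negative net monetary benefit `WTP × ΔE − ΔC`. With the published
uncertainty almost all sampled relative risks are protective, so the curve
is monotone and crosses 50% near the deterministic ICER.

## The microsimulation oracle

`simulate_individuals()` replays the identical decision tree child by
child: per cycle, Bernoulli progression draws, then for cavitated children
a two-stage chance node (treatment allocation, then success/failure).
`microsim_summary()` applies the same reward schedule and discounting as
the cohort engine. Because the cohort model is exactly the expectation of
this process, every cohort quantity must lie within a few standard errors
of its microsimulation estimate; the tests assert 3 SEs at the baseline
(100,000 children, giving an SE of ≈ 0.0016 on the end-state proportions,
small enough to separate the published rounded percentages) and 4 SEs
across 20 random valid parameter sets at 20,000 children.
`random_parameter_set()` draws probabilities in realistic ranges (e.g.
progression 0.02–0.15 per cycle, relative risk 0.5–1.0) with closed chance
nodes, so the equivalence is exercised away from the published baseline
too.

What the generator does *not* emulate: between-child risk heterogeneity,
time-varying caries risk, tooth-level outcomes (20 teeth per child),
adverse events, and dropout. Passing tests therefore show the engines are
internally consistent and correctly implement the published tree — not that
the tree captures those real-data features.

## Numerical choices and degenerate inputs

Row sums of transition matrices are enforced to 1 within 1e-12 and
occupancy conservation within 1e-10. A zero-width CI degenerates a fitted
distribution to a fixed value, as does a beta fit whose `α + β` exceeds
1e9; a CI too wide for a beta (variance ≥ m(1−m)) is an error rather than a
silent truncation. A zero incremental effect flags the ICER as undefined
and decides dominance on cost alone. `n_cycles = 0` returns the initial
distribution. Display rounding (two decimals for currency) happens only in
printed reports; all stored values are unrounded.

## Known limitations

* The accrual scheme is a documented reconstruction; the published per-arm
  accumulated totals are reproduced only in their internal arithmetic
  (increments, ICERs, the R$33 per child-year figure), not as model
  outputs.
* Parameters are sampled independently in the PSA; no correlation structure
  between, e.g., the two restoration success probabilities is imposed,
  because none was published.
* The analysis inherits the single-payer, single-lesion, child-level
  perspective; societal costs, QALYs and subgroup (high-risk) analyses are
  out of scope.
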