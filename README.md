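# fvcea

Decision-analytic cost-effectiveness modelling of semiannual professional
fluoride-varnish (FV) application in preschool children, compared with
standard preventive care (oral hygiene instruction and dietary counselling),
from the perspective of a Brazilian supplemental-health payer with costs in
2022 Reais. The package is aimed at health-economics and dental public-health
researchers who want a fully scripted, testable counterpart to
spreadsheet/TreeAge cohort models.

## The model

Children enter at age 2 in a three-state discrete-time Markov model with
6-month cycles over a 4-year horizon (8 cycles):

- **no cavity** → **cavity** with per-cycle probability *p* = 0.06873;
- **cavity** is treated within the cycle through a chance node — glass
  ionomer restoration (*q* = 0.873, success 0.63), Hall-technique crown
  (*q* = 0.004, success 0.98), or extraction (complement, always resolves) —
  successful treatment moves the child to **previous cavity**, failure keeps
  the child in **cavity**;
- **previous cavity** → **cavity** (relapse) with probability 0.28.

The FV arm multiplies four probabilities (no-cavity→cavity, both restoration
failure probabilities, and the relapse probability) by the pooled relative
risk RR = 0.88 (95% CI 0.81–0.95) and adds an application cost of R$78 per
cycle. Costs and outcomes are discounted at 5% per year. Strategies are
compared by the incremental cost-effectiveness ratio
ICER = ΔC/ΔE with dominance classification, under four effectiveness
definitions (probability of ever developing a cavity, cavity-free time,
expected new cavities, DALYs at a 0.01 annual disability weight).

Uncertainty is handled by a one-way deterministic sensitivity analysis
(tornado over each parameter's 95% CI, costs at ±20%), and a probabilistic
sensitivity analysis (Monte-Carlo over beta-distributed probabilities,
gamma-distributed costs with CV 20%, and a lognormal relative risk) with
cost-effectiveness acceptability curves. An individual-level
microsimulation of the same decision tree serves as a brute-force oracle:
its per-child means must agree with the cohort engine within Monte-Carlo
error, which the test suite asserts at baseline and on random parameter
sets.

## Worked example

```r
library(fvcea)
ps <- load_parameter_table()          # packaged published parameter table

propagate(build_transition_model(ps, "standard"), 8)
#> Cohort trajectory, 8 cycles, arm: standard
#> End occupancy: no_cavity 0.5657, cavity 0.1580, previous_cavity 0.2762

run_cea(ps, mode = "ever_cavity_avoided")
#> Cost-effectiveness comparison (ever_cavity_avoided)
#>   standard care:   cost     973.15  effect 0.5657244
#>   care plus FV:    cost    1513.90  effect 0.6070708
#>   incremental:     cost     540.75  effect 0.0413464
#>   ICER: 13078.48 Reais per unit (no dominance)
```

After 8 cycles, 57% of the standard-care cohort is still caries-free versus
61% with varnish (16% vs 13% cavitated, 28% vs 26% with past caries): FV
prevents a cavity in about 4 of every 100 children over the 4 years. Under
the package's accrual scheme (routine visit cost every cycle, expected
treatment costs, and the R$78 application every cycle on the FV arm), that
protection costs R$540.75 extra per child, i.e. R$13,078 per child kept
cavity-free — far above the R$60 willingness to pay per cavity avoided a
Brazilian study reports for private payers.

```r
head(tornado(ps, "ever_cavity_avoided"), 2)
#>    parameter  icer_low icer_high     width increases_icer
#> 7     eff_rr  7950.955  32618.24 24667.28           TRUE
#> 12      c_fv 10369.667  15787.29  5417.62           TRUE

psa <- run_psa(ps, n_iter = 1000, seed = 1)
ceac(psa, outcome = "cavity")    # acceptance probability over a WTP grid
```

The varnish relative risk is by far the most influential parameter, and the
acceptability curve crosses 50% only near the deterministic ICER.

A command-line wrapper with subcommands `run-cea`, `run-dsa`, `run-psa`,
`microsim` and `validate-params` ships in `inst/cli/fvcea.R`:

```sh
Rscript inst/cli/fvcea.R run-cea --out results/
```

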