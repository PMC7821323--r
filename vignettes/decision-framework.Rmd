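---
title: "An expected-value decision framework for insect pest management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An expected-value decision framework for insect pest management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipmecon)
```

## The problem and the model

Soybean aphid outbreaks in the US Midwest are sporadic: in the Iowa
insecticide-trial record underlying the bundled preset, populations
exceeded the economic threshold before growth stage R6 in 43.5% of
site-years, and an unmanaged outbreak cost on average 12.7% of yield on
aphid-susceptible varieties. Pyrethroid-resistant aphid populations add a
second layer of uncertainty: the cheapest insecticide may simply fail.
`ipmecon` evaluates coded management scenarios by expectation rather than
simulation, because every quantity the decision needs — expected yield,
expected cost, expected net revenue — is a finite mixture over a small
outcome tree.

A scenario combines five choices: variety aphid trait (S susceptible /
R resistant), variety herbicide trait (H herbicide-tolerant /
C conventional), spray policy (X none / P prophylactic / T
threshold-based), scouting (N none / E efficacy / M monitoring) and pest
type (W wild-type / I insecticide-resistant). The expected yield fraction
is

$$EY = p_n + p_o \sum_{t \in \{w,s,c\}} p_t \left[ I(\text{effective}_t)
  + q\, I(\text{no mgmt}_t \lor \text{ineffective}_t) \right],$$

and expected net revenue is $E(R) = E(Y)\,E(P) - E(C)$ with yield and price
treated as independent. Only variable costs enter $E(C)$ by default, so
$E(R)$ compares scenarios (a partial budget) rather than measuring farm
profitability; `include_fixed = TRUE` adds the fixed items (tillage,
herbicide application, planting, two early scouting passes, harvest, land
rent — US$847.09/ha in the 2018 preset), which shift every scenario by the
same constant and never change a ranking or threshold.

### The effectiveness rule engine

Rather than hard-coding the eight case-study scenarios, outcomes per pest
class are derived from rules: an aphid-resistant variety is always
effective; with a susceptible variety and no application the outcome is
"no management"; otherwise management is effective iff at least one applied
insecticide belongs to a group the realized pest class does not survive.
Resistance profiles are data (`wild = {}`, `resistant = {3A}`,
`cross_resistant = {3A, 1B}` by default), so new insecticide groups or pest
classes extend the model without code changes. The rescue (second)
application is counted as applied only when efficacy scouting is part of
the scenario *and* the class survives the first application's group — a
farmer only re-sprays after observing a failure. At most two applications
can occur. An exhaustive outcome-tree expansion
(`enumerate_outcomes()`) serves as a brute-force oracle; the test suite
checks closed form against tree on a thousand random parameter draws.

## Parameters and defaults (Iowa 2018 preset)

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| attainable yield | 3537 | kg/ha | ten-year Iowa average |
| q (S varieties) | 0.873 | — | fraction retained on unmanaged loss (12.7% loss) |
| q (R varieties) | 1 | — | virulent biotypes excluded by default |
| crop price | 0.33 | US$/kg | 2018 Iowa market price (ten-year low) |
| p_outbreak | 0.435 | — | high-risk-location outbreak frequency |
| insecticide (mean / 1B / 3A / 4C) | 22.88 / 21.98 / 13.83 / 61.78 | US$/ha | 2018 regional product survey |
| application | 20.02 | US$/application | custom-rate survey |
| scouting | 10.50 | US$/activity | 2 early (fixed), 6 monitoring, 1–2 efficacy |
| seed S.H / S.C / R.C | 155.13 / 117.65 / 111.56 | US$/ha | 2018 catalog means |
| herbicide H / C | 89.70 / 118.61 | US$/ha | product cost by trait |

Design choices where the inputs left the design open:

* **Insecticide pricing convention.** Wild-type (-W) scenarios price the
  application at the mean across all surveyed products (US$22.88) since no
  particular class is implied; insecticide-resistance (-I) scenarios price
  class-specifically (pyrethroid 3A first, organophosphate 1B rescue —
  farmers use the cheapest effective product). This is the only convention
  that reproduces the wild-type 29% spray threshold and the 48%/57%
  resistance thresholds simultaneously.
* **Seed cost for aphid-resistant varieties.** The preset uses the survey
  mean over all aphid-resistant varieties (US$111.56/ha), giving
  `E(R) = 937.04` for the RCXN scenario versus the published US$934.37 — a
  0.3% residual attributable to rounding in the published yield, price and
  seed means (the alternative Rag1+Rag2-conventional mean, 114.37, is kept
  in the config under `seed_alternatives` and gives 934.23). The choice is
  a config field, not code.
* **Prophylactic applications in no-outbreak years.** Calendar-based sprays
  are tank-mixed at flowering regardless of aphid pressure, so the P policy
  incurs the first application's cost with expected count 1 (it cannot
  affect yield in a no-outbreak year, only cost); threshold-based sprays
  (T) incur it with probability p_o. The prophylactic tank-mix is costed at
  the full US$20.02 application charge: no cost-sharing rule with the
  fungicide pass is assumed.
* **q_R is a configuration field.** Aphid biotypes virulent on resistant
  varieties exist but are rare; the default q_R = 1 excludes them while the
  config hook allows exploring q_R < 1 without modeling biotype dynamics.
* **Grammar vs availability.** "Threshold sprays require monitoring" and
  "efficacy scouting follows an application" are grammar rules; "no
  aphid-resistant herbicide-tolerant seed" is 2018 market availability and
  lives in the config's availability table.

## Solvers and numerical choices

$E(R)$ is affine in the outbreak probability and in the resistant-class
probability (at most one rescue, fixed mix of the remaining classes), so
break-even crossings are solved exactly from two endpoint evaluations;
every interior crossing is cross-checked against a bisection root
(`uniroot`, tolerance 1e-12) and a disagreement beyond 1e-9 is an error,
not a warning. Parallel revenue lines return no crossing with a
diagnostic. Probability sums are validated to 1e-12; violations name the
offending block. Reported integer percentages round half-up, matching how
the case-study thresholds are quoted. Sweeps default to 0.1 probability
increments (`grid$step`), but thresholds never come from grids.

Reference values under the preset: spraying beats no management above a
28.94% outbreak probability; at p_o = 0.435 a single pyrethroid loses to no
management above 47.51% resistance (56.69% at the US$0.40/kg average
price); the tech-fee analysis puts the resistant-variety-vs-no-management
crossing near 15% (the published figure, >18%, depends on supplementary
cost details not in the printed tables, so the package asserts only the
0.10–0.25 interval). Likewise the published ">88%" and "<63%" thresholds
for the two-application program imply a second-application cost structure
(≈US$121/ha) that cannot be decomposed from the printed tables; under this
package's component-sum rescue cost (US$52.50/ha) the SHPE-I vs SHXN-I
baseline crossing happens to land at 88.2%. These are documented rather
than calibrated.

## Sensitivity analyses

`sensitivity_run()` modifies exactly one factor and recomputes thresholds
and sweeps: `yield_low`/`yield_high` (3026 / 4035 kg/ha, the ten-year state
extremes), `price_avg`/`price_high` (US$0.40 / 0.52 per kg), `tech_fee`
(the herbicide-tolerance seed premium, 155.13 − 117.65 = US$37.48/ha,
applied to aphid-resistant seed) and `input_scale_88` (all input costs
× 0.88, the largest ten-year input-cost decline). Directional behavior is
asserted in the tests: thresholds fall with higher yield, higher price and
lower input costs, and rise with lower yield.

```{r sensitivity, eval = FALSE}
sensitivity_run(load_config(), "price_avg")$thresholds
```

## The synthetic site-year generator

The outbreak-frequency (43.5%) and yield-loss (12.7%) estimators operate on
site-year trial records (untreated yield U, best treated yield H, outbreak
flag), with loss = 100 − (U/H)×100. The original 23-site-year Iowa trial
set is not publicly deposited, so `generate_fixture_records()` provides a
synthetic stand-in: Bernoulli outbreak flags, outbreak-year losses from a
normal truncated to [0, 60]% (default mean 12.7, sd 6 — a coefficient of
variation typical of multi-site efficacy trials; the source data constrain
only the mean), near-zero noise losses otherwise, and H drawn around
3537 kg/ha. It emulates marginal frequencies, not the spatial or temporal
correlation of real site-years, so passing round-trip tests show estimator
correctness, not field realism; synthetic records are never used to accept
published numbers. Negative computed losses (untreated out-yielding
treated) are preserved, not clipped.

## Problem sizes and limitations

All computations are closed-form expectations; the test suite's largest
jobs are 1000 random outcome-tree comparisons, 500 randomized solver
cross-checks and a 10,000-record generator round-trip, chosen to exercise
the properties at negligible cost. Known limitations: single-season
snapshot (no resistance evolution, discounting or inflation); no aphid
resurgence or seed-applied insecticides; outbreak is a given flag, not a
population-dynamics output; cross-resistance scenarios are configurable but
outside the bundled eight; and the decision space is the discrete scenario
set — no continuous optimization over spray timing or rates.
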