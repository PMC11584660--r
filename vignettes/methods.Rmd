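---
title: "Methods: a Markov cost-effectiveness model for DR screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cost-effectiveness model for DR screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drcea)
```

## The decision problem

A primary-care screening programme for diabetic retinopathy photographs
the retinas of people attending diabetes clinics, refers those with
suspect or ungradable images to secondary care, and treats what it finds:
laser photocoagulation for sight-threatening diabetic retinopathy (STDR)
and surgery for incidentally detected cataract. The programme's benefit is
avoided blindness and restored vision quality; its cost is the whole
cascade from camera capital to the patient's bus fare. `drcea` implements
the cohort model, the cost ledger and the uncertainty analyses needed to
judge the trade, with the 2019 Kerala pilot programme pinned as the
built-in replication scenario (`kerala_2019_scenario()`).

## Disease progression model

Three states: **STDR**, **blind**, **dead** (absorbing), in annual cycles
with ages advancing alongside cycles from a cohort entry age of 59 (the
average age of the STDR patients in the pilot scenario). There is no
recovery from blindness and no inflow of new disease; the model values
treatment for a cohort already diagnosed with STDR.

Within a cycle, death acts first and progression applies to survivors:

* `p_dead = min(rr × qx(age), 1)`, with `qx` the general-population annual
  death probability and `rr` the state's mortality relative risk —
  `rr_diabetes = 1.9` in the STDR state, `rr_blind = 2.34` in the blind
  state;
* `p_blind = p_prog × (1 − p_dead)`, with `p_prog = 0.09` untreated and
  `0.02` under laser treatment;
* `p_stay = 1 − p_dead − p_blind`.

This death-first ordering makes each transition row sum to exactly one
with no renormalisation; the tests assert row sums to within 1e−12 and
cohort-trace conservation to within 1e−10 over the full horizon.

The blind-state relative risk of 2.34 applies to the general-population
rate and *replaces* the diabetes uplift rather than stacking on top of it;
that is the literal reading of "additional excess mortality in blindness"
alongside a printed 2.34 multiplier on the general rate, and the milder
default. The multiplicative alternative (1.9 × 2.34) is available via
`model_params(blind_uplift_combined = TRUE)`. Likewise the uplift
multiplies the annual death *probability* (capped at 1), which is the
plain reading of an uplift on a mortality rate; a hazard-scale version
`1 − (1 − qx)^rr`, which never needs capping, is available via
`uplift_scale = "hazard"`.

## Outcomes

**Life expectancy** is the sum over cycles of the proportion alive at the
end of each cycle. No half-cycle correction is applied by default — the
convention is stated rather than hidden, and `half_cycle = TRUE` switches
to averaging start- and end-of-cycle occupancy. **Discounted QALYs** weight
occupancy by state utilities (`u_stdr = 0.70`, `u_blind = 0.55` on a
EuroQoL scale) and discount at 3% per year starting at cycle one, so the
first year's benefit is discounted once:

$$QALY = \sum_{t=1}^{H} \left[ occ_S(t)\,u_S + occ_B(t)\,u_B \right](1+r)^{-t}.$$

The per-person **laser treatment gain** is the difference in discounted
QALYs between the treated and untreated arms. It is positive whenever
treatment lowers the blindness transition and sight carries more utility
than blindness, and the tests verify it is monotone non-increasing in the
treated transition probability.

The per-person **cataract surgery gain** assumes surgery does not change
survival: an annual utility gain of `u_gain_cataract = 0.20`, declining by
`hrqol_decline = 0.07%` per year of age, is enjoyed over discounted
survival under the diabetes-uplifted life table:

$$gain = \sum_{t=1}^{H} u_{gain}\,(1-\delta)^t\,S(t)\,(1+r)^{-t}.$$

The age-related utility decline is applied only to the cataract gain, not
to the STDR/blind utilities, because it is described only for the cataract
pathway; `stdr_utility_decline = TRUE` extends it to the Markov states.
The cataract cohort enters at the same age, 59, as the STDR cohort — the
only age given — and both are configurable.

The horizon defaults to the life-table terminal age (everyone dead), as
"lifetime" QALYs require; a fixed `horizon` is accepted for closed-form
checks.

## Validation of the cohort engine

Two independent oracles guard the propagation arithmetic in the test
suite. A seeded individual-level microsimulation (10^5 individuals,
written against the model description rather than the package's transition
code) must match the cohort trace within three Monte-Carlo standard errors
per state per cycle. And on an age-constant-mortality table the discounted
QALY sum must match the fundamental-matrix closed form
$x_0^\top \delta Q (I-\delta Q)^{-1} (I-(\delta Q)^{H}) u$ to 1e−9.

## Costing

The ledger is bottom-up and itemised; every line carries a stage
(screening, examination, laser, cataract) and a payer (health-system or
societal), totals are exact sums of lines, and the full economic cost is
the sum of both payer perspectives. Camera capital (16 cameras at
INR 300,000) is annuitized over a five-year lifetime with the
annuity-immediate factor at 3% — the same rate used to discount benefits,
chosen because it reproduces the scenario's reported annual camera cost of
slightly over one million — and 0% (straight-line) is available. All
arithmetic stays at full precision; `round_inr()` exists purely for
presentation (per-patient figures to the nearest INR 5, stage totals to
0.1 million), and reports flag rounded values as presentation-only.

Cascade counts can be derived from branch rates
(`cascade_from_rates()`, round-half-to-even) but explicit counts override
the derived ones with a logged discrepancy: programme reports often print
counts whose ratios do not reproduce them exactly (31% of 5307 is 1645,
not the printed 1662), and the printed counts are authoritative in the
replication scenario.

The bilateral scenario adds one extra laser package — a health-care cost
only, no extra attendances — for a configurable fraction of laser
patients (`bilateral_fraction = 0.20` reproduces the reported scenario).

## Decision rule

The comparator is explicit: no screening, zero cost, zero QALYs, under
the assumption that without the programme these patients would have lost
their sight. The ICER is the full-precision ratio of programme cost to
total QALYs; a zero-QALY denominator yields an `NA` flagged indeterminate
rather than an error. Classification against GDP per capita
(INR 144,000) uses strict inequalities — "costs less than" — so a ratio
exactly at a boundary falls into the less favourable band. Component QALY
totals are also reported with integer rounding (224 + 290 = 514 in the
replication scenario) for parity with customary reporting; ratios always
use unrounded values.

## Sensitivity analysis

**One-way (tornado).** Each registry parameter — utilities, the HRQoL
decline rate, the two transition probabilities, the blindness relative
risk, the screening cost per person and the two treatment unit costs —
moves to ±10% of its central value, everything else held central.
Excursions that would push a probability or utility outside [0, 1] are
clipped to the boundary with a warning rather than rejected. The table is
sorted by descending ICER span; a failed leg flags its parameter `NA` and
the run continues.

**Probabilistic.** Each parameter gets a moment-matched distribution with
SD equal to 25% of its central value: gamma (shape `(μ/σ)² = 16` under the
25% rule, scale `σ²/μ`) for unit costs and the blindness relative risk,
beta (method-of-moments, with the variance bound `σ² < μ(1−μ)` enforced by
a named error) for utilities and probabilities. Draws are independent
across parameters — no correlation structure is imposed — and each
parameter has its own child stream seeded from the root seed, so adding a
parameter never perturbs the others' draws and results are reproducible
bit-for-bit. Cascade counts stay fixed; the uncertainty analysed is in
model and unit-cost inputs. A drawn treated transition rate may exceed the
drawn untreated rate (no ordering is imposed by default);
`psa_spec(enforce_ordering = TRUE)` resamples such iterations.

The CEAC reports, at each willingness to pay, the fraction of iterations
with positive net monetary benefit `wtp × QALYs − cost`. One consequence
of independent sampling is worth stating: because a sampled treated rate
can exceed the untreated rate and a sampled STDR utility can fall below
the blind utility, a small fraction of iterations has negative total
QALYs, so the CEAC asymptote at large willingness to pay is the
probability of positive QALYs (about 0.97 in the replication scenario),
not exactly 1. With all SDs at zero the ICER cloud collapses onto the
deterministic ICER and the asymptote is exactly 1.

In the replication scenario the deterministic ICER is about one seventh
of the INR 144,000 threshold, and the measured probability of
cost-effectiveness at that threshold is about 95% (binomial Monte-Carlo
SE ≈ 0.2 percentage points at 10,000 iterations). Published analyses of
this programme type report lower probabilities when treatment-state
utilities are sampled as separate quantities whose difference can go
negative; this package samples the single cataract gain parameter its
model defines, and the resulting probability is what the acceptance
script reports.

## Synthetic inputs

The model needs a national life table that is not distributable with the
package, so `synth_life_table()` generates a deterministic single-year
stand-in from a Gompertz–Makeham hazard `μ(x) = c + a·e^{bx}` with
`c = 0.003`, `a = 4.97e−5`, `b = 0.095` over ages 18–105. The two
components are interpretable (a flat background risk plus exponentially
rising senescent mortality), adult `qx` is monotone, and closed forms are
easy to test. The parameters were calibrated once so that remaining life
expectancy at age 59 under the 1.9 diabetes uplift is ≈ 12.6 years — the
realistic magnitude for this cohort — and then frozen. What the synthetic
table does *not* emulate: infant/child mortality (ages below 18 are
absent), the accident hump, sex differences, and the exact shape of any
national schedule. Model outputs on this table (life expectancies around
11.8/12.3 years, per-person gains around 0.64/1.95) are therefore
magnitude checks, not replications; dropping in a real single-year or
abridged national table via `read_life_table()` is the route to exact
replication. Tests passing on the synthetic table demonstrate the
arithmetic and the orderings, not the calibration of any real population.

`synth_cascade()` complements it with a stochastic cascade: sequential
seeded binomial thinning (referral → attendance → diagnosis → treatment,
with ungradable images branching to cataract surgery), whose expected
counts are the cumulative products of the branch probabilities. It
exercises the costing code on realistic random inputs; it does not model
covariates, clustering by health centre, or pandemic-era attrition.

## Numerical conventions and degenerate inputs

* Transition rows: exact sum to 1 (asserted at 1e−12); occupancy
  conservation at 1e−10; a per-cycle clamp guards occupancies against
  accumulation roundoff at the 1e−16 level.
* Life tables must be contiguous single years after expansion; abridged
  bands expand by repeating the band `qx` (no interpolation — the simplest
  faithful choice when no interpolation rule is given). A table ending
  before age 110 without `qx = 1` gains a terminal age one year after its
  last row, with a warning.
* `qx = 1` everywhere kills the cohort in one cycle and gives zero life
  expectancy; zero rates and zero utilities propagate to exact zeros; a
  zero-QALY ICER is flagged, never a crash.
* Problem sizes in the shipped tests: 10^5-individual microsimulation,
  10^6-draw moment checks, 10,000-iteration PSA — together they run in a
  few seconds.

## Known limitations

* No progression from non-sight-threatening DR into STDR, no bilateral
  vision states, no treatment waning or repeat laser cycles.
* The comparator assumes zero counterfactual treatment; partial
  counterfactual uptake would lower the incremental QALYs.
* Follow-up consultations after treatment and second-year screening costs
  are out of the ledger's scope.
* QALYs are used directly against a threshold phrased per DALY; no
  QALY–DALY conversion is attempted.
* PSA draws are independent across parameters; correlated sampling
  (Cholesky/copula) is not implemented.
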