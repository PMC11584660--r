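# drcea

Cost-effectiveness analysis of diabetic retinopathy (DR) screening
programmes, built around the evaluation of a 2019 pilot screening programme
run in primary-care Family Health Centres in Kerala, India.

Screening for sight-threatening diabetic retinopathy (STDR) followed by
laser photocoagulation slows progression to blindness; a screening visit
also picks up cataract cases that would otherwise go untreated. The package
answers the health-economic question: given the cost of the whole screening
cascade (cameras, training, staff, referrals, eye examinations, treatment)
and the lifetime quality-adjusted life years (QALYs) gained by the people
treated, is the programme cost-effective against a GDP-per-capita
willingness-to-pay threshold?

## The model

**Disease progression.** A three-state annual-cycle Markov cohort model
with states STDR, blind, and dead (absorbing). At each cycle the cohort,
entering at age 59, faces

- a death probability `min(rr × qx, 1)`, where `qx` is the
  general-population annual death probability from a life table and `rr` is
  a mortality relative risk: 1.9 in the STDR state (excess mortality with
  diabetes) and 2.34 in the blind state;
- among survivors of the STDR state, an annual transition to blindness of
  9% untreated or 2% under laser photocoagulation.

Health-state utilities are 0.70 (STDR) and 0.55 (blind). Discounted
lifetime QALYs per arm are

```
QALY = Σ_t [occ_STDR(t)·u_STDR + occ_blind(t)·u_blind] · (1+r)^(−t),   r = 3%
```

and the per-person treatment gain is the treated-minus-untreated
difference. Cataract surgery is assumed not to change survival; its gain is
an annual utility increment of 0.20 declining by 0.07% per year, summed
over discounted survival under the diabetes-uplifted life table.

**Costing.** A bottom-up ledger of the 2019 cascade (5307 screened, 1662
referred, 830 examined, 345 laser-treated, 160 cataract operations):
annuitized camera capital, staff training, per-screen staff/admin/community
health worker costs, eye-examination staff plus travel and opportunity
costs, and treatment packages (laser INR 12,000 over three attendances,
cataract surgery INR 18,000, plus INR 950 societal cost per secondary-care
attendance). Every line is tagged health-system or societal; totals are
exact sums, and rounding happens only at presentation.

**Decision metrics.** ICER = total cost / total QALYs versus a
do-nothing comparator (zero cost, zero QALYs — without screening these
patients are assumed to lose their sight), classified against 1× and 3×
GDP per capita (INR 144,000) with strict inequalities. One-way sensitivity
analysis (±10% excursions, tornado table) and probabilistic sensitivity
analysis (10,000 iterations; gamma distributions for unit costs and the
blindness mortality relative risk, beta for utilities and transition
probabilities, SD = 25% of the central value) with a cost-effectiveness
acceptability curve.

Because the national life table behind the published analysis is not
shipped with the package, a calibrated Gompertz–Makeham synthetic life
table stands in by default; any single-year or abridged `age,qx` CSV can be
dropped in via `read_life_table()`.

## Worked example

```r
library(drcea)
sc  <- kerala_2019_scenario()   # pinned central estimates
rep <- run_scenario(sc)
rep
#> Run report: scenario "kerala_2019"
#>
#> Cost-effectiveness result (comparator: no screening, zero cost and QALYs)
#>   total cost:  INR 11.3 million
#>   total QALYs: 533 (221 laser + 312 cataract; unrounded 532.52)
#>   average QALY gain per person treated: 1.054 (n = 505)
#>   ICER: INR 21,131 per QALY -> highly cost-effective (GDP per capita 144,000)
#>
#>   life expectancy at 59: 11.83 yr untreated, 12.33 yr treated
#>   per-person QALY gain: 0.640 laser, 1.947 cataract
```

The report reads: the whole programme cost INR 11.3 million (including
INR 1.9 million of societal costs to patients and attendants); on the
synthetic life table the model puts the per-person discounted lifetime gain
at 0.64 QALYs for laser treatment and 1.95 for cataract surgery, so the 505
people treated gain about 533 QALYs and the programme costs about
INR 21,000 per QALY — about one seventh of GDP per capita, i.e. firmly
"highly cost-effective".

Sensitivity analysis:

```r
tor <- one_way_dsa(sc)          # ±10% one-way excursions
head(as.data.frame(tor), 3)
#>         parameter low_icer high_icer    span
#> 1          u_stdr  24652.1   18490.0 6162.13
#> 2         u_blind  19186.6   23513.8 4327.26
#> 3 u_gain_cataract  22444.1   19963.0 2481.09

draws <- run_psa(sc)            # 10,000 seeded Monte Carlo iterations
prob_cost_effective(draws, wtp = 144000)$probability
#> [1] 0.9471
```

The quality-of-life utilities dominate the tornado; treatment unit costs
matter less. A command-line wrapper with `run`, `dsa`, `psa` and `synth`
subcommands lives at `inst/cli/drcea.R`.

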