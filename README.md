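# her2cea

Cost-utility and budget-impact modelling of neoadjuvant dual HER2-targeted
therapy for early HER2-positive breast cancer in Sri Lanka.

## The problem

Dual HER2-targeted neoadjuvant therapy (trastuzumab combined with pertuzumab
or lapatinib, plus chemotherapy) improves event-free survival over single
trastuzumab therapy, but the drug acquisition costs are a serious obstacle
for lower-middle-income health systems. This package implements, as tested
and reusable code, the decision model used to weigh that trade-off for the
Sri Lankan public healthcare system: which of five neoadjuvant/adjuvant
treatment sequences is cost-effective at a willingness-to-pay of one GDP per
capita (LKR 758,680 per QALY, 2021), what price reduction would change the
answer, and what each option would do to the national budget.

It is written for health-economics analysts: every computation step (engine,
ICERs, sensitivity analyses, budget impact) is an exported, documented,
tested function; the `analysis/` scripts chain them into the full study.

## The model

A five-state Markov cohort model with monthly cycles from age 50 to 100:

- **States**: event free (EF), locoregional recurrence (LRR), metastasis
  (MET), remission (REM), death (absorbing). A cohort enters entirely in EF.
- **Transitions**: EF leaves for an event with per-cycle probability *q(t)*,
  split 25% LRR / 75% MET, and to death at the age-matched general-population
  rate *m(age)*. LRR resolves within one cycle (to REM 0.96619, MET 0.02317,
  death 0.01064). REM relapses to MET at 0.0076/month and dies at *m(age)*.
  MET dies at 0.04672/month.
- **Efficacy**: intervention strategies scale the event hazard by their
  network-meta-analysis hazard ratio, HR 0.54 (0.32–0.91) for the
  pertuzumab strategies and 0.85 (0.60–1.22) for the lapatinib strategies,
  via the rate transform `p' = 1 − (1 − p)^HR`, for at most 12 years.
- **Valuation**: life-years and utility-weighted QALYs (EF 0.81 in year 1
  then 0.85; LRR 0.72; REM 0.82; MET 0.70), state costs on the appropriate
  clock (EF on model time, LRR/REM on time-in-state, MET flat), one-time
  neoadjuvant treatment costs at cycle 0, and 3% annual discounting,
  `d(t) = 1.03^(−t/12)`. The public perspective counts direct medical costs;
  the societal perspective adds direct non-medical costs.
- **Decision metrics**: ICER `ΔC/ΔE` pairwise and sequentially along the
  ascending-cost frontier with dominance assessment; net monetary benefit
  `E·λ − C` for the acceptability curves.

Around the deterministic engine sit a probabilistic sensitivity analysis
(Beta/Gamma/log-normal parameter sampling, 1,000 Monte Carlo iterations),
a one-way tornado analysis, a threshold price-reduction search, and a
five-fiscal-year budget impact analysis driven by national epidemiology
(13,647 prevalent and 4,447 incident breast cancer cases, 66% early stage,
22% HER2-positive, 20% or 60% coverage).

## Worked example

```r
library(her2cea)

ps <- base_case_parameters()      # the full packaged parameter set
tab <- ce_table(ps, "public")     # deterministic results, incremental analysis
tab[, c("strategy", "total_ly", "total_qaly", "total_cost_lkr",
        "icer_vs_comparator_lkr", "sequential_icer_lkr")]
```

```
  strategy total_ly total_qaly total_cost_lkr icer_vs_comparator_lkr sequential_icer_lkr
1       S1    8.983      7.373        3035038                     NA                  NA
2       S3    9.554      7.866        3292170                 521652              521652
3       S5   10.055      8.299        4282646                1347651             2288277
4       S2   11.061      9.168        5030087                1111460              859903
5       S4   12.773     10.646       10893115                2401090             3967585
```

Reading this: the comparator (S1, neoadjuvant trastuzumab + chemotherapy)
yields 8.98 discounted life-years, 7.37 QALYs and a lifetime cost of
LKR 3.04M per patient. Only S3 (neoadjuvant lapatinib + trastuzumab,
adjuvant trastuzumab) buys QALYs below the LKR 758,680 threshold
(LKR 521,652 per QALY). S5 is extendedly dominated: its sequential ICER
exceeds that of S2, the next strategy up the cost ordering.

```r
thr <- threshold_reduction(ps, "S2", "S1", "societal", step = 0.05)
thr$reduction        # 0.25 — a 25% neoadjuvant price cut makes S2 cost-effective
threshold_reduction(ps, "S4", "S1", "societal")$achievable  # FALSE

bia <- run_bia(ps, coverage = 0.6)
bia[bia$strategy == "S2" & bia$year == 1, c("incremental_lkr", "budget_ratio")]
#   incremental_lkr  budget_ratio
#        3436986012        2.7819   # +LKR 3,437M in year 1; 2.78x the comparator
```

The numbered scripts under `analysis/` run the complete study and write all
tables to `results/`:

```sh
Rscript analysis/01_base_case.R
Rscript analysis/02_threshold.R
Rscript analysis/03_dsa.R
Rscript analysis/04_psa.R --seed 1 --n 1000
Rscript analysis/05_budget_impact.R
```

## Validation

The cohort engine is cross-checked against an independent patient-level
microsimulation (`microsim_oracle()`) that replays the same transition
structure trajectory-by-trajectory, on the base case and on randomly
generated model configurations (`random_model()`), and against closed-form
solutions on degenerate models (`two_state_model()`). See the methods
vignette (`vignettes/markov-cohort-model.Rmd`) for the modelling
conventions, calibration decisions and known limitations.
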