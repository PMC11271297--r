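---
title: "Methods: the Markov cohort model behind her2cea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Markov cohort model behind her2cea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(her2cea)
```

## The decision problem

Five treatment strategies for early HER2-positive breast cancer are
compared: single HER2 blockade (neoadjuvant trastuzumab + chemotherapy,
adjuvant trastuzumab; S1, the comparator) against four dual-blockade
sequences that add pertuzumab (S2, S4) or lapatinib (S3, S5) in the
neoadjuvant phase, continuing either single (S2, S3) or dual (S4, S5)
blockade in the adjuvant year. Outcomes are discounted life-years, QALYs and
lifetime costs per patient; decisions are framed as ICERs against a
willingness-to-pay of LKR 758,680 per QALY (one 2021 GDP per capita of Sri
Lanka, USD 3,815 at 194.78 LKR/USD).

## Model structure and assumptions

The cohort starts at age 50, entirely event free, and is propagated in
1-month cycles to age 100. States are event free (EF), locoregional
recurrence (LRR), metastasis (MET), remission (REM), and death.

Structural assumptions inherited from the clinical setting:

* chemotherapy backbones are identical across arms and do not affect
  outcomes;
* a locoregional recurrence happens at most once — a second locoregional
  failure is treated as metastatic disease;
* patients in remission are disease free, so their background mortality is
  the general female population's (as is EF's);
* the death state absorbs both cancer and non-cancer deaths.

Transition rows are built per cycle (`transition_distribution()`):
background mortality competes additively with disease transitions in the EF
and REM rows, the stay probability absorbs the remainder, and the engine
raises a hard error if exits exceed 1 rather than silently truncating. The
LRR exit probabilities printed for this model sum to exactly 1
(0.02317 + 0.01064 + 0.96619), so LRR is in effect a one-cycle tunnel; its
"year 2 onwards" cost piece is implemented (time-in-state clock) but
unreachable at base-case values.

## Efficacy composition

The published inputs give (a) per-strategy baseline EF→event transition
probabilities — a constant 0.01015/month for the adjuvant-trastuzumab
strategies, trial-derived time-dependent values for S4
(0.00118/0.00229/0.00220/0.00220 across years 1–4+) and S5 (0.00798) over
months 0–60 — and (b) network-meta-analysis hazard ratios versus the
comparator (0.54 for pertuzumab, 0.85 for lapatinib strategies), with a
maximum effect duration of 12 years. How these compose is a genuine design
choice, and the package makes it explicit via `efficacy_mode`:

* **`hr_on_baseline`** (default): the hazard ratio scales the strategy's own
  baseline schedule via `p' = 1 − (1 − p)^HR` for the full 144-month effect
  window; afterwards every strategy reverts to the common 0.01015 baseline.
* `baseline_then_hr`: S4/S5 use their trial baselines unscaled for months
  0–60, then the HR-scaled common baseline to month 144.
* `hr_throughout`: the HR on the common baseline only, ignoring trial
  schedules.
* `trial_only`: printed baselines with no HR.

The default was chosen by calibration against the published base-case table:
with `hr_on_baseline` the engine reproduces the published life-years and
QALYs of all five strategies to within about 1.4% (S4/S5 to within 0.5%),
whereas the alternatives understate the benefit of the dual-adjuvant
strategies by 2–5%. The cost of this choice is conceptual: for S4/S5 the
hazard ratio acts on top of baselines that already derive from dual-therapy
trials, so part of the effect may be counted twice. We accept that because
the published results are evidently produced under it; analysts who prefer a
conservative reading can switch modes in one line.

## Valuation conventions

* **Cycle-start accrual, no half-cycle correction.** State membership at the
  start of cycle *t* earns 1/12 life-year, its utility weight / 12 in QALYs,
  and one month of state cost. With 1-month cycles the half-cycle correction
  is negligible relative to the parameter uncertainty. A consequence worth
  noting: a cohort facing certain death in its first cycle still accrues
  1/12 life-year (`two_state_model(1)`), and the engine, the
  microsimulation and the closed form all agree on that convention.
* **Cost clocks.** EF costs follow the model clock (the strategy-specific
  adjuvant-year monthly DMC in months 0–11, then the follow-up schedule:
  years 2–5, 6–10, 10+). LRR and REM costs follow time-in-state (tenure),
  tracked by tunnel buckets capped at 121 months — every piece beyond 120
  months shares the "after year 10" cost, so the cap loses nothing while
  bounding the state space. MET cost is flat. Neoadjuvant treatment costs
  are one-time, charged undiscounted at cycle 0.
* **Discounting** multiplies cycle-\(t\) amounts by \((1+r)^{-t/12}\) with
  \(r = 3\%\) per year for both costs and outcomes (separately
  configurable, which the tornado analysis exploits).
* **Perspectives.** Public healthcare system = direct medical costs only;
  societal additionally includes direct non-medical costs (transport,
  caregiving, food). Indirect productivity costs are excluded.

## Parameters and sampling distributions

All parameters live in a flat named vector with a distribution table
(`base_case_parameters()`), serialisable to YAML/JSON with optional CSV
tables (`write_parameter_set()`, `load_parameter_set()`). Distribution
families follow standard health-technology-assessment practice:

* probabilities, shares and utilities: **Beta**, parameterised by method of
  moments from (mean, SE) — `beta_from_mean_se()`;
* costs: **Gamma**, method of moments — `gamma_from_mean_se()`;
* hazard ratios: **log-normal**, with `mu = log(point)` and `sigma` from
  the printed 95% CI width on the log scale — `lognormal_from_ci()`.

Standard errors are 10% of the mean for transition probabilities and costs;
utilities carry their published SEs (0.0102–0.0266), which take precedence
over the 10% rule. Discount rates, the clock and the exchange rate are
never sampled.

Joint draws (`sample_parameter_set()`) treat parameters as independent, with
two structural exceptions: the metastatic event share is the complement of
the sampled locoregional share (they must sum to 1), and an LRR exit row
drawn above the probability simplex is renormalised to sum to 1, with the
number of renormalisations reported. Independent Beta draws of the
life-table bands can violate monotonicity in age; the draw is repaired with
a running maximum, a negligible upward bias confined to adjacent bands. The
PSA derives one sub-seed per iteration from the root seed, so iteration
\(i\)'s draw does not depend on how many iterations precede it.

## Sensitivity and budget analyses

* **Tornado** (`one_way_dsa()`): each parameter in turn is set to the
  2.5th/97.5th percentile of its sampling distribution (hazard ratios: the
  printed CI bounds; discount rates: 0% and 6%, common practice where the
  source is silent; a ±20% convention is selectable). When an LRR exit is
  varied, the remission exit — the row's complement — absorbs the change so
  the row stays on the simplex. Dominance reversals at a bound (the
  lapatinib HRs cross 1) are flagged, with the signed ratio retained rather
  than dropped.
* **Threshold analysis** (`threshold_reduction()`): scales the strategy's
  neoadjuvant-phase cost as accounted in the analysis perspective (DMC,
  plus the neoadjuvant DNMC under the societal perspective) by \(1-r\) and
  searches the smallest \(r\) on a 5% grid (bisection to 0.1% is
  available) with ICER at or below the threshold. The optional
  `ADJUVANT_EF_YEAR1` component scales the strategy's adjuvant-year monthly
  DMC excess over its single-adjuvant counterpart (S4 over S2, S5 over S3)
  — the dual-continuation drug cost.
* **Budget impact** (`run_bia()`): undiscounted public-perspective per-cycle
  cost streams from the engine, multiplied by the treated cohorts — year 1
  covers prevalent + incident cases, later years the incident cohort only,
  all filtered by 66% early-stage, 22% HER2-positive and the coverage level
  — with each cohort's stream aligned to its start year and summed per
  fiscal year. Budgets are undiscounted, standard for affordability
  analysis. Year 2–5 attribution is the least-specified part of the source
  analysis; the implementation keeps all previously treated cohorts'
  continuing state costs on the books, which tracks the published year-2+
  figures qualitatively but not exactly.

## Validation instruments

`microsim_oracle()` simulates individual monthly trajectories with the same
transition rows, tenure bookkeeping and valuation conventions as the cohort
engine; agreement within 3 Monte-Carlo standard errors on life-years, QALYs
and costs is enforced in the test suite on the base case (200,000 patients)
and on twenty seeded random configurations (8,000 patients each, horizons of
8 years). `random_model()` generates those configurations: structurally
valid parameter sets with randomised schedules, optionally with recurrence
pathways switched off (2–5 reachable transient states) to exercise corner
topologies. `two_state_model()` reduces the engine to a geometric series
with a closed form checked to 1e-12.

What the synthetic generator emulates is the parameter *shape* of the real
problem — piecewise-constant monthly probabilities, tenure-dependent cost
schedules, distribution specs — not clinical realism: its values are drawn
from broad uniform/log-normal ranges, so passing tests demonstrate the
machinery is correct, not that any synthetic configuration resembles breast
cancer epidemiology. Conclusions about the actual decision problem rest on
the packaged base case.

## Numerical choices

* Cohort mass is conserved to 1e-10 over all 600 cycles and transition rows
  sum to 1 within 1e-12 (tested).
* Exit probabilities exceeding 1 are a hard error everywhere (engine,
  transition rows), never a silent clamp; float-level negatives (> −1e-12)
  are clamped to zero.
* CEAC ties (identical NMB across strategies in a draw) split probability
  equally; at the default parameters ties do not occur.
* `sample_parameter_set()` retries a bounded number of times (100) before
  failing; at base-case parameters the first draw is essentially always
  valid.
* Problem sizes in the test suite — 1,000 PSA iterations, 200,000
  microsimulated patients for the base-case check, 8,000 per synthetic
  configuration — were chosen so Monte-Carlo standard errors are small
  relative to the tolerances being enforced.

## Known limitations

* Lifetime costs run 3–5% above the published totals (life-years and QALYs
  within ~1.4%), concentrated in the metastasis cost stream; the unrounded
  survival-derived inputs behind the published table are not printed, so
  closer agreement is not attainable from the published inputs alone. All
  decision-relevant quantities (orderings, threshold reductions, budget
  ratios) are insensitive to this gap.
* The efficacy composition is a calibrated choice (see above); the
  conservative modes give the dual-adjuvant strategies materially less
  benefit.
* Year 2–5 budget attributions are approximate (see budget impact above).
* No adverse-event states, no individual-level heterogeneity (dosing by
  weight/body surface area is already embedded in the cost inputs), no
  value-of-information analysis, and no market-dynamics or inflation
  projection in the budget model.
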