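---
title: "Modelling primary vs secondary G-CSF prophylaxis of febrile neutropenia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling primary vs secondary G-CSF prophylaxis of febrile neutropenia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fncea)
```

## The decision problem

Febrile neutropenia (FN) is a common, costly and occasionally fatal
complication of myelosuppressive chemotherapy. Granulocyte
colony-stimulating factors (G-CSFs; short-acting filgrastim, long-acting
pegfilgrastim) roughly halve the per-cycle FN risk, and biosimilar
competition has cut their prices. The policy question this package models:
for patients at *intermediate* baseline FN risk (10–20% over the course),
is giving a biosimilar G-CSF from cycle 1 (**primary prophylaxis, PP**)
good value compared with waiting for a first FN event and covering the
remaining cycles (**secondary prophylaxis, SP**)? The package evaluates
this for breast cancer (BC), non-small cell lung cancer (NSCLC) and
non-Hodgkin lymphoma (NHL) cohorts under Austrian, French and German cost
and discounting settings.

## Model structure

The model is a hybrid cohort model with three parts.

**Chemotherapy phase.** Cycle 1 is a decision tree; cycles 2–6 form a
Markov cycle tree over the states {alive without FN history, alive with FN
history, dead}, with 3-week cycles. Each cycle a patient may have at most
one FN event; every FN event is an inpatient admission incurring a lump
hospitalisation cost and a case-fatality probability applied at the end of
the cycle. All chemotherapy-phase deaths are FN deaths. FN survivors carry
a history flag that (a) multiplies their later FN risk by the FN-history
relative risk, and (b) under SP, triggers G-CSF from the next cycle
onwards. Under PP everyone alive receives G-CSF every cycle.

**Per-cycle risk.** The inputs give one course-level FN probability
$P_{\text{total}}$ and a relative risk $r$ of FN in cycles 2+ versus
cycle 1 (without history). The cycle-1 probability $p_1$ solves

$$1 - (1 - p_1)\,(1 - r\,p_1)^{\,n-1} = P_{\text{total}}$$

on the no-history, no-prophylaxis path (`calibrate_cycle1_risk()`, bracketed
bisection, residual $<10^{-10}$). The conditioning on the no-history path
is a modelling choice: patients who have had FN follow the
history-multiplied risk instead, so the realised course-level risk in the
no-prophylaxis arm is slightly above $P_{\text{total}}$. Relative risks
(history, prophylaxis) act multiplicatively on per-cycle *probabilities*
and are clamped at 1.

**Post-chemotherapy phase.** Annual Markov cycles over a lifetime horizon.
At entry, survivors split once into low/high relative-dose-intensity (RDI)
strata with probabilities conditional on their ever-FN status (the
history mix is carried exactly). For 20 years the annual death probability
is background mortality $q_x(\text{age},\text{sex})$ *plus* the
cancer-specific annual excess, multiplied by a hazard ratio in the low-RDI
stratum, clamped at 1; from year 21 patients are considered cured and
revert to background mortality alone. Post-chemotherapy costs are excluded
(they do not differ by prophylaxis strategy); neither are chemotherapy
drug costs or G-CSF adverse events modelled.

**Outcomes.** Discounted cost, life years (LY), quality-adjusted life
years (QALY: LY weighted by state utilities — during chemotherapy, during
an FN admission, first post-chemotherapy year, later years), FN events and
FN deaths per patient. Incremental results PP − SP yield ICERs per FN
event avoided, per LY and per QALY, with dominance classified when PP is
cheaper and better on all measures (`incremental()`).

## Accrual and discounting conventions

Discounting is mid-period: a cash flow or utility accrued in chemotherapy
cycle $k$ is discounted at $(k-\tfrac12)\times 21/365.25$ years, and
post-chemotherapy year $k$ at $t_{\text{chemo}} + k - \tfrac12$ years.

Two deliberately different accrual conventions are used, and both are
enforced by tests:

* *Chemotherapy cycles* (3 weeks): deaths occur at the end of the cycle
  and decedents accrue that cycle's utility and costs. At this granularity
  the FN admission itself (length of stay at the FN utility, remainder of
  the cycle at the chemotherapy utility) is the dominant quality-of-life
  event and should be captured for decedents too.
* *Post-chemotherapy years*: year $k$ is accrued by its end-of-year
  survivors, so with a flat hazard $q$ and discount rate $d$ the
  discounted life expectancy is exactly the annuity
  $\sum_{k\ge1} (1-q)^k (1+d)^{-(k-1/2)}$. At annual granularity this
  survivor-weighting approximates deaths occurring mid-year and keeps the
  closed form exact, which the test suite exploits.

No additional half-cycle correction is applied on state occupancy.

The FN hospitalisation cost is a lump sum per event; length of stay (LOS)
affects only the utility weighting of the FN cycle. This keeps LOS a live
sensitivity input, which matters because it is one of the more influential
one-way drivers.

## Parameter uncertainty

Published ranges are interpreted as central 95% intervals — the
convention has to be chosen because the source does not state min–max vs
interval, and 95% is the common reading:

* **Beta** (probabilities, utilities): moment matching with mean = base
  and sd = (high − low)/3.92. The NHL FN case-fatality range with a 0.0
  lower bound is fitted the same way, no special-casing.
* **Lognormal** (relative risks, hazard ratios): log-mean = log(base),
  log-sd = (log high − log low)/3.92. The published intervals are nearly
  log-symmetric around their base values, so the fitted 2.5th/97.5th
  percentiles land within ~3% of the printed bounds.

The PSA (`psa()`) draws every parameter with a published distribution
jointly and independently per iteration, shares the draw between the PP
and SP arms, and evaluates the full model per draw. Design details:

* Per-iteration RNG substreams are derived from the seed and the iteration
  counter, so results do not depend on the order in which parameters are
  evaluated.
* No correlation structure is imposed (none is published). The one
  structural ordering — P(low RDI | FN history) ≥ P(low RDI | no history)
  — is restored by swapping the two draws when a sample inverts it,
  which preserves the inequality without inventing a copula.
* Prophylaxis-effect draws at or above 1 are clamped just below 1 and
  counted; above 1% clamping triggers a warning. With the published
  intervals, clamping is essentially never observed.
* Costs, LOS, weight and discount rates have no published distributions
  and stay fixed in the PSA; they are varied in the one-way analysis.

The one-way analysis (`owsa()`) re-runs the base case at each parameter's
bounds and ranks by the swing of the cost-per-QALY ICER, with dominant
results mapped to 0 on the ICER scale. One-way-only ranges are modelling
choices: ±20% for the two calibrated costs, 4–10 days LOS (base 6),
60–90 kg patient weight (base 70), 0–5% discount rate.

## The synthetic calibration layer

Two inputs behind the published analysis are not redistributable and are
replaced by a synthetic, clearly-labelled layer:

**Costs.** Unit-cost tables are unavailable, but total discounted cost per
strategy is exactly linear in the two unknown cost inputs:
$C = g\,A + h\,B$, where $g$ is the G-CSF cost per cycle, $h$ the FN
hospitalisation cost, $A$ the expected discounted number of prophylaxis
cycles delivered and $B$ the expected discounted number of FN events. The
published PP and SP cost totals of each country × cancer × agent block
therefore identify $(g, h)$ through a 2×2 linear system
(`calibrate_costs()`; condition number checked, negative solutions
rejected). Clinical parameters are never tuned. For filgrastim the solved
$g$ is stored back as a derived price per 300-µg vial — dosing is
5 µg/kg rounded up to whole vials, five administrations per cycle (the
administration count is configurable; it is not published) — so that
patient weight stays a live sensitivity input through vial rounding.
Pegfilgrastim is one fixed-price dose per cycle. Solved filgrastim
per-cycle costs across the 18 blocks land between about €180 and €580,
i.e. within single-digit multiples of the €55.54 scenario list price
quoted for Austria, which is the sanity band the tests enforce. The FN
hospitalisation cost is calibrated per block; blocks of the same country
can disagree (the underlying tariffs are unknown), and the calibration
report records each solved value rather than reconciling them.

**Life tables.** National life tables are emulated by a synthetic
Gompertz generator, $q_x = 1 - \exp(-a e^{b x})$, with per-country
baseline hazards (Austria $a = 2.5\times10^{-5}$, France
$2.1\times10^{-5}$, Germany $2.4\times10^{-5}$; $b = 0.1$; female scaling
0.5; terminal age 110, giving life expectancies at birth in the low 80s).
Files in the `age,sex,qx` text format are also accepted.

**Cohort profiles.** Entry ages and sex mixes are not published beyond
"varied according to cancer type"; the fixtures use BC 50 years/100%
female, NSCLC 65/35%, NHL 60/45%. Discount rates follow national
health-technology-assessment conventions: Austria 5%, France 2.5%,
Germany 3%, applied to costs and effects alike. The pegfilgrastim
prophylaxis relative risk (0.25) has no published interval; its PSA range
scales the filgrastim interval proportionally (0.179–0.339).

Because entry ages, sex mixes, national life tables and discount rates
are all fixture choices, the *absolute* LY and QALY columns of the
published tables are not reproduced and are not claimed; the bundled
fixtures land within roughly 1–2 QALYs of the printed absolute values
while matching the printed cost cells to < €0.5 by construction.
Incremental effects, which drive the ICERs, are much less sensitive to
these choices: the base cases land within a few thousandths of a QALY of
the printed incremental values.

## Validation strategy

With the absolute LY/QALY surface out of reach, correctness rests on a
property battery run by the test suite:

* a patient-level microsimulation (`simulate_individuals()`) of the
  identical event logic agrees with the cohort engine within 3 Monte-Carlo
  standard errors on cost, LY, QALY and FN events for every fixture and
  strategy, at $10^6$ patients in the end-to-end battery and $2\times10^5$
  in the per-module tests;
* occupancy is conserved to $10^{-12}$ after every cycle; QALY ≤ LY
  everywhere, including under PSA draws;
* zero discounting reproduces undiscounted totals, and totals fall
  strictly as the rate rises;
* the flat-hazard annuity closed form holds to $10^{-9}$; with zero
  disease risk the engine returns the life-table curtate life expectancy
  plus the chemotherapy duration;
* the risk calibration residual is below $10^{-10}$ with an exact
  round-trip of the course-level risk, and the rate-based mortality
  conversion round-trips to $10^{-12}$;
* calibration round-trips: synthetic cost targets are recovered to
  $10^{-6}$ €, and all 36 published cost cells to < €0.5.

The probabilistic headline — PP cost-effective at €50,000/QALY in at
least 95% of 1000 iterations for every filgrastim scenario — is
recomputed from scratch by `scripts/acceptance.R` and by the test suite
(observed minimum ≈ 96–97%, in the German BC block, where incremental
costs are highest).

## Numerical choices and degenerate inputs

* Root finding: `uniroot` on a bracket $[0, \min(1, 1/r)]$ followed by a
  bisection polish; absence of a root in the bracket (course risk too
  high for the cycle structure) is a calibration error, not a silent
  clamp.
* All composed probabilities (risk × RR products, background + excess
  mortality) are clamped to $[0,1]$ at the point of use.
* Ages are handled in whole years; the ~0.35-year chemotherapy phase does
  not advance age for life-table lookup.
* The calibration system is rejected when its exact condition number
  exceeds $10^6$; in practice the PP/SP coefficient rows are far from
  collinear (PP is drug-cycle-dominated, SP FN-event-dominated).
* Patients beyond the life-table terminal age are absorbed at $q_x = 1$.

## Known limitations

* Cohort-level only: no individual risk scoring (the underlying evidence
  is regimen-level), no outpatient FN management, no G-CSF adverse
  events, no relapse/progression tunnel states.
* At most one FN event per cycle.
* The synthetic life tables are smooth parametric stand-ins; infant
  mortality, accident humps and country detail are absent, which is
  acceptable here because cohorts enter at ages 50–65.
* Calibrated costs inherit any structural misfit of the model: they are
  *the* costs that make this model reproduce the published totals, not
  measured tariffs.
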