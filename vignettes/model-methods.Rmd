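---
title: "Model methods: population-based BRCA1/BRCA2 testing cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model behind `compare_strategies()`: its
structure, assumptions, parameterization, numerical conventions, the
synthetic epidemiology it is packaged with, and the design choices made
where published sources leave the design open. It states no empirical result
beyond what the test suite and `scripts/acceptance.R` compute.

## Decision problem

Two strategies for women entering at age 30 (configurable):

* **FH-based testing** (reference): only the ~0.98% of women meeting
  clinical-criteria/family-history thresholds are offered BRCA1/BRCA2
  testing; carrier prevalence is 10% among them and 0.58% among the rest.
* **Population testing**: every woman is offered the test (sensitivity and
  specificity 0.9995 at base; 97% sensitivity as a scenario).

Detected pathogenic-variant (PV) carriers choose among risk-reducing
mastectomy (RRM, age 37), risk-reducing salpingo-oophorectomy (RRSO, age 40),
and chemoprevention, independently at uptakes 0.359, 0.628 and 0.086; 80% of
RRSO uptakers take HRT to age 51. Everyone else receives general-population
screening. The prevalence mixture identity
`P(FH)·prev(FH) + (1−P(FH))·prev(noFH) ≈ prev(overall)` is asserted at load
(observed agreement: 0.006723 vs 0.0067, 0.35% relative).

## Markov engine

Annual cycles from the entry age to 83. Public states: Well; early/advanced/
remission/recurrence/terminal breast (BC) and ovarian (OC) cancer; deaths
from BC, OC, coronary heart disease (CHD) and other causes (all absorbing;
no BC/OC co-occurrence, reflecting the rarity of synchronous disease).
Internally the five post-diagnosis years are one-year *tunnel states*, so the
annual cancer-specific death probability `1 − S5^(1/5)` (from stage-specific
5-year survival) applies for exactly five cycles; survivors then enter
remission and face background mortality plus an annual recurrence
probability. Cancer deaths pass through a one-year terminal state carrying
the terminal-care cost and utility.

Within-cycle competition between BC incidence, OC incidence, fatal excess
CHD and background mortality is resolved on the rate scale:
`r_i = −ln(1−p_i)`, total event probability `1 − exp(−Σr)`, allocated
proportionally to rates. Every transition-matrix row must sum to 1 within
1e-12 and every occupancy vector to 1 within 1e-9; violations raise errors —
probabilities are never silently clipped. No half-cycle correction is
applied (annual-cycle convention); transitions happen at cycle end, event
costs are booked in the cycle of occurrence, and entry-age costs (testing,
counselling) are undiscounted at cycle 0. Discounting is 1.5%/yr for costs
and health outcomes alike.

An individual-level microsimulation (`microsimulate_cohort()`, chained
multinomial draws through the identical matrices) serves as an independent
stochastic oracle; the test suite requires cohort occupancy to agree within
4 binomial standard errors at every cycle with 200,000 simulated women.

## Interventions and hazards

RRSO multiplies the OC hazard by 0.04 from the RRSO age. The BC hazard is
multiplied by 0.09 after RRM alone, 0.49 after RRSO alone and 0.05 after
both, each component active from its surgery age (between ages 37 and 40 an
RRM+RRSO uptaker carries the RRM-alone multiplier); chemoprevention
contributes a further ×0.71 during its 5-year window from entry. Components
compose multiplicatively and are capped at 1. Age intervals are half-open:
"HRT until 51" means the last HRT year is age 50; screening "30 to 49"
includes 49.

**Excess CHD.** RRSO without HRT carries an annual excess CHD risk of 0.0072
(fatal fraction 0.0303) from the RRSO age until the HRT stop age (51), plus
an annual morbidity cost of CAD 175 while well in that window. Whether the
published 0.0072 is an annual or a cumulative excess is ambiguous; treating
it as annual over that window is the single most result-sensitive assumption
here, and the no-HRT scenario exercises it.

**Surgery disutility window.** The utility multipliers for RRM (0.88) and
RRSO (0.95) compose multiplicatively with state utilities (a Well year after
both surgeries scores 0.836 while both windows are active) and apply for a
configurable recovery window after each surgery, default one year
(`schedules$rrm_disutility_years`, `rrso_disutility_years`). This is a
deliberate design choice: applying chronic lifelong decrements makes both
surgeries strongly net QALY-negative, which inverts the direction of every
published comparison of this kind (prevention arms gain QALYs in all
scenarios) and is arithmetically incompatible with per-carrier QALY gains of
the reported magnitude. Users studying chronic post-surgical disutility can
lengthen the windows.

**Test errors and VUS.** False negatives behave as undetected carriers.
False positives receive posttest counselling and the full detected-carrier
management — surveillance and uptake costs applied to general-population
hazards, i.e. costs without carrier-level benefit (a conservative reading).
Variants of uncertain significance (VUS, probability 0.02 among tested
non-carriers — an assumption, as is the 0.005 lifetime reclassification
hook) receive posttest counselling and no intervention before
reclassification.

## Costs, utilities, perspectives

All costs in 2022 CAD. One-time: test 220, counselling 167 per session
(pretest for all tested; posttest for PV/VUS/false-positive results), RRM
12,330, RRSO 4,901, BC diagnosis/treatment 33,155, OC 21,800, terminal care
43,638 (BC) / 52,697 (OC), fatal CHD 4,839. Annual: BC 1,414
(general-population tariff) or 1,284 (carrier tariff, chosen by true carrier
status), OC 7,300 in post-diagnosis years 1–2 and 7,010 in years 3–5
(recurrence years use the year-1–2 tariff; remission carries no annual
cancer cost), HRT 680, chemoprevention 293, excess-CHD morbidity 175.
Screening: mammography 144, MRI 130; general population biennial mammography
50–74; detected carriers annual mammography 40–69 plus annual MRI 30–49,
truncated at the RRM age for RRM uptakers (no breast surveillance after
mastectomy). Scheduled costs after entry are weighted by the probability of
still being Well when due.

Utilities: Well 1; BC early 0.71, advanced 0.65, recurrent 0.45, remission
0.81, terminal 0.16; OC 0.81/0.55/0.61/0.83/0.16. Composed utilities are
capped at 1 at accrual time.

The **societal perspective** adds human-capital productivity losses against
age-specific earnings × employment, zero from the retirement age (65):
temporary disability (90% of diagnosed women absent half a year), permanent
disability (7% earnings reduction while alive in post-diagnosis states), and
premature mortality (the discounted foregone-earnings stream from cancer or
excess-CHD death to retirement). Background deaths generate no productivity
loss, so the add-on reflects modelled disease only. The payer perspective
excludes all of it.

## Parameter uncertainty

Each parameter carries a variation rule — its 95% CI where published,
otherwise ±10% (probabilities, utilities) or ±30% (costs) — used both for
one-way analysis bounds and to derive the PSA standard error
(`SE = (high−low)/3.92` for CIs, `0.10·base/1.96` or `0.30·base/1.96` for
percentage rules). PSA families are beta for probabilities (moment-matched;
infeasible matching is an error), gamma for costs (`shape = (m/SE)²`,
`scale = SE²/m`) and log-normal for utility multipliers, matched on the
natural scale so the distribution mean equals the base value. Log-normal
draws are *not* truncated — truncation would bias the sampled mean below
base, breaking mean-preservation — and utility validity is instead enforced
at the point of use by the accrual cap at 1. Utilities reported as mean (SD)
(RRM 0.88 (0.22), RRSO 0.95 (0.10)) are converted to a ±1.96·SD range
truncated to [0, 1]. Parameters are drawn independently (no published
correlation structure); one master seed spawns a per-draw substream so PSA
results are independent of execution order. The CEAC grid runs 0–150,000 in
steps of 1,000 CAD/QALY, covering both conventional thresholds (50,000 and
100,000).

Threshold analyses invert the ICER by bisection after numerically asserting
monotonicity over the bracket: the *maximum* testing cost (ICER increases
with cost; bracket 0–5,000 CAD) and the *minimum* combined PV prevalence
(ICER decreases as prevalence rises; the knob moves overall prevalence,
holds P(carrier|FH) at 0.1 and re-derives P(carrier|noFH) from the mixture
identity; the bracket floor keeps that conditional nonnegative). Bisection
stops when the ICER is within 0.25 CAD of the target. The search reports its
own direction explicitly because the natural reading of a cost-effectiveness
constraint gives a *minimum* prevalence, and published threshold-prevalence
figures of this kind are not internally consistent in direction or scale.

## Synthetic epidemiology

`generate_inputs("canada_like")` emulates the inputs a national analysis
takes from cancer statistics and life tables:

* piecewise-constant incidence over registry-style age bands, with the last
  open band frozen at the 71–80 value (the model's assumption for ages over
  80);
* general-population curves rising to ~0.41% (BC) and ~0.033% (OC) per year,
  giving lifetime risks near 11.6% and 1.0% by 80;
* carrier curves following the published penetrance pattern (steep rise
  through the 30s and a midlife plateau for BC; OC taking off after 40),
  scaled by a single calibration factor (found by root-finding on the crude
  cumulative risk `1 − Π(1−p)`) to hit the midpoints of the published
  lifetime-risk bands: 0.665 for BC (band 0.61–0.72) and 0.325 for OC
  (0.17–0.48); carrier incidence is floored at the general-population curve;
* a Gompertz female life table `q(a) = 3.5e-4 · e^(0.082(a−30))`;
* 5-year survival 0.88 (BC) and 0.44 (OC) with stage splits at diagnosis of
  70/30 (BC) and 30/70 (OC) early/advanced — flagged assumptions; the
  advanced-stage survival is derived so the stage mixture reproduces the
  overall figure (0.95/0.717 for BC, 0.85/0.264 for OC); annual recurrence
  from remission 0.015 (BC) and 0.04 (OC);
* flat earnings of CAD 52,000 to 65 with employment 0.82/0.70/0.50 across
  ages 30–54/55–59/60–64.

The generator is deterministic; the seed argument is reserved for future
perturbation profiles. The `null_risk` preset zeroes all cancer incidence
and is used for degeneracy checks (with strategy-differentiating costs and
uptakes zeroed, the two arms produce identical results exactly).

What the synthetic tables do **not** emulate: cohort effects and secular
trends in incidence and survival, BRCA1/BRCA2 heterogeneity (a single
combined-carrier curve is used), stage-specific survival detail beyond the
two-way split, and registry sampling noise. Passing tests therefore
demonstrate the *machinery* — conservation, discounting, competing risks,
aggregation, sampling — and the qualitative economics, not agreement with
any national registry; for substantive estimates users should supply real
tables via `read_epi_tables()` in the documented CSV schema.

## Scenario conventions

Testing at age *a* > 30 moves model entry to *a* (the cohort is cancer-free
at entry, discounting re-bases to cycle 0 at *a*) with both surgeries in the
next cycle, per the stated convention for entry above the median surgery
ages. The older-surgery scenario uses RRM 48 / RRSO 50 following the primary
text; the variant RRM 49 / RRSO 50 that appears in tabulated form elsewhere
is exposed as `late_surgery_49`. "No BC benefit of RRSO" sets the RRSO-alone
BC multiplier to 1 and the RRM+RRSO multiplier to the RRM-alone value,
removing exactly the RRSO contribution.

A structural note on orderings: with fixed prevalence, cancer-free entry and
next-cycle surgery, a carrier detected at 40 benefits from prevention with
probability 1, whereas an entry-30 carrier benefits only if still
cancer-free at ages 37/40; the model can therefore yield a *lower* ICER at
entry 40 than at 30 even though ICERs rise steeply at 50+. Reproducing a
monotone increase from age 30 onward requires mechanisms outside the printed
structure, such as carrier-prevalence depletion with age or age-declining
surgical uptake.

## Problem sizes and runtime conventions

The packaged analyses use: 53 annual cycles (ages 30–83); ~30 distinct
hazard pathways per dual-arm comparison (memoized by pathway); 500 PSA draws
in the tests and acceptance script (the `psa_draws` setting defaults to
5,000 for production runs); 200,000 women in the microsimulation oracle;
bisection to 0.25 CAD on thresholds. Cohort results are deterministic;
every stochastic component (PSA, microsimulation) takes an explicit seed.

## Known limitations

Cascade testing of relatives, male carriers and multigene panels are out of
scope. Uptake is age-constant; VUS reclassification is a cost/probability
hook only; screening confers no stage-shift benefit (it is costed, not
modelled as early detection); CHD excess is the window assumption above;
productivity losses cover the three human-capital components only. Currency
is 2022 CAD throughout; no conversion is applied.
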