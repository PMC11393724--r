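# brcacea

Decision-analytic cost-effectiveness model of **population-based BRCA1/BRCA2
genetic testing** for women, compared with the current standard of testing
only women who meet clinical-criteria/family-history (FH) thresholds.

About 1 in 150 women carries a pathogenic variant (PV) in *BRCA1* or *BRCA2*,
with lifetime breast-cancer risks of roughly 61–72% and ovarian-cancer risks
of 17–48% by age 80 — yet FH-based criteria identify only a small fraction of
carriers before cancer occurs. Identified carriers can lower those risks
through risk-reducing mastectomy (RRM), risk-reducing salpingo-oophorectomy
(RRSO), chemoprevention and intensified surveillance. Whether offering the
test to *every* woman is worth the extra testing cost is a health-economics
question, and this package implements the standard machinery to answer it:

* a **decision tree** that classifies women by FH status, carrier status and
  test result (PV, VUS, negative, false positive) and assigns prevention
  packages at published uptake rates;
* an **annual-cycle Markov cohort model** over ages 30–83 with states
  {Well, early/advanced/remission/recurrence/terminal breast and ovarian
  cancer, cancer deaths, coronary (CHD) death, other-cause death}, annual
  transition probabilities built from age-specific incidence, 5-year survival
  and a national life table, and within-cycle competing risks combined on the
  rate scale (`p_i' = r_i / Σr · (1 − e^(−Σr))`, `r = −ln(1−p)`);
* lifetime **discounted costs, life-years and QALYs** (1.5%/yr) from payer
  and societal perspectives, the societal one adding human-capital
  productivity losses (temporary and permanent disability, premature
  mortality before retirement);
* the **incremental cost-effectiveness ratio** ICER = ΔC/ΔE against
  willingness-to-pay thresholds of CAD $50,000 and $100,000 per QALY, and the
  net monetary benefit λ·ΔE − ΔC;
* **uncertainty analyses**: one-way (tornado) variation over 95% CIs or
  ±10%/±30% ranges, probabilistic sensitivity analysis with moment-matched
  beta (probabilities), gamma (costs) and log-normal (utilities)
  distributions, cost-effectiveness acceptability curves, and bisection
  threshold analyses on the testing cost and the PV prevalence;
* a **scenario grid**: testing at ages 40–70, older surgery ages, no
  breast-cancer benefit of RRSO, no HRT, half surgical uptake, 97% test
  sensitivity.

Because the age-indexed incidence, life-table and survival inputs come from
national statistics that cannot be redistributed here, the package ships a
**synthetic-inputs generator** (`generate_inputs()`) whose carrier curves are
calibrated to the published cumulative-risk bands, plus a documented CSV
schema (`write_epi_tables()` / `read_epi_tables()`) so real registry tables
can be substituted.

## Worked example

```r
library(brcacea)

ps  <- load_parameters()          # packaged base-case configuration
epi <- generate_inputs(seed = 1)  # synthetic Canadian-style epidemiology
res <- compare_strategies(ps, epi)
res
#> <comparison_result> population-based vs FH-based BRCA1/2 testing
#>   payer    dC = 378.56, dQALY = 0.01275, ICER = 29 686.10 CAD/QALY
#>   societal dC = 225.17, dQALY = 0.01275, ICER = 17 657.75 CAD/QALY
#>   per million: 1256 BC and 491 OC diagnoses prevented, 321 BC and 365 OC
#>   deaths averted, 2 excess CHD deaths
```

Reading: testing every woman costs an extra CAD $379 per woman (payer) and
buys 0.0128 QALYs, i.e. about CAD $29,700 per QALY — below the conventional
CAD $50,000 willingness-to-pay threshold, so population testing is
cost-effective under these inputs; from the societal perspective prevented
productivity losses cut the ratio to about $17,700. Per million women tested
at age 30, roughly 1,260 breast cancers and 490 ovarian cancers are
prevented, at the price of a couple of excess CHD deaths after
premenopausal oophorectomy without HRT.

Scenarios, sensitivity analyses and figures:

```r
run_scenario("half_rrso", ps, epi)              # half RRSO uptake (31.4%)
tornado(ps, epi, c("cost_genetic_testing", "prevalence_no_fh", "uptake_rrso"))
draws <- run_psa(ps, epi, n_draws = 500, seed = 1)
prob_cost_effective(draws, 50000, "payer")
render_figures(draws, ceac(draws), "figures")
threshold_search(ps, epi, "test_cost", lambda = 50000, perspective = "payer")
```

## Package layout

| file | contents |
| --- | --- |
| `R/params.R` | parameter loading/validation, PSA distribution fitting, one-way variation |
| `R/synthetic_inputs.R` | synthetic incidence/life-table/survival/productivity inputs, CSV schema |
| `R/strategy.R` | decision tree, intervention uptake, hazard modifiers, dated cost events |
| `R/markov.R` | state space, competing risks, transition matrices, cohort engine, microsimulation oracle |
| `R/accrual.R` | utilities/costs per state, discounting, productivity losses |
| `R/outcomes.R` | strategy aggregation, ICER, net benefit, per-million impact |
| `R/uncertainty.R` | tornado, PSA, CEAC, threshold analyses |
| `R/scenarios.R` | named scenario grid |
| `R/io.R` | CSV/JSON result writers, figures |
| `vignettes/model-methods.Rmd` | model assumptions, calibration and design choices |
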