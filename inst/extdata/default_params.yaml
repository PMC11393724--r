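# Default model configuration: base-case analysis settings, intervention
# schedules, and every probability / cost (2022 CAD) / utility the model uses.
# Parameters without a published range carry `rule` and `source: assumption`.
settings:
  discount_rate: 0.015
  wtp_thresholds: [50000, 100000]
  start_age: 30
  horizon_age: 83
  cohort_scale: 1.0e+06
  psa_draws: 5000
  perspective: payer
  seed: 1

schedules:
  rrm_age: 37
  rrso_age: 40
  rrm_disutility_years: 1
  rrso_disutility_years: 1
  hrt_stop_age: 51
  chemoprevention_start_age: 30
  chemoprevention_duration_years: 5
  retirement_age: 65
  screening:
    general:
      mammography: {start: 50, stop: 74, every: 2}
    carrier:
      mammography: {start: 40, stop: 69, every: 1}
      mri: {start: 30, stop: 49, every: 1}

probabilities:
  prevalence_overall:          {base: 0.0067, low: 0.0059, high: 0.0077, rule: ci}
  prevalence_fh:               {base: 0.1, rule: pct10}
  prevalence_no_fh:            {base: 0.0058, low: 0.0051, high: 0.0068, rule: ci}
  p_fh:                        {base: 0.0098, low: 0.0047, high: 0.0179, rule: ci}
  uptake_rrm:                  {base: 0.359, low: 0.287, high: 0.431, rule: ci}
  uptake_rrso:                 {base: 0.628, low: 0.502, high: 0.754, rule: ci}
  uptake_chemoprevention:      {base: 0.086, low: 0.069, high: 0.103, rule: ci}
  hrt_compliance:              {base: 0.8, low: 0.76, high: 0.83, rule: ci}
  rrso_oc_reduction:           {base: 0.96, low: 0.80, high: 0.96, rule: ci}
  hr_bc_rrso:                  {base: 0.49, low: 0.37, high: 0.65, rule: ci}
  rrm_bc_reduction:            {base: 0.91, low: 0.62, high: 0.98, rule: ci}
  rrm_rrso_bc_reduction:       {base: 0.95, low: 0.78, high: 0.99, rule: ci}
  hr_bc_chemoprevention:       {base: 0.71, low: 0.60, high: 0.83, rule: ci}
  chd_excess_risk:             {base: 0.0072, low: 0.0068, high: 0.0076, rule: ci}
  chd_fatal_fraction:          {base: 0.0303, low: 0.011, high: 0.043, rule: ci}
  test_sensitivity:            {base: 0.9995, rule: fixed}
  test_specificity:            {base: 0.9995, rule: fixed}
  vus_probability:             {base: 0.02, rule: pct10, source: assumption}
  vus_reclassification_probability: {base: 0.005, rule: fixed, source: assumption}

costs:
  cost_genetic_testing:        {base: 220}
  cost_genetic_counselling:    {base: 167}
  cost_rrso:                   {base: 4901}
  cost_rrm:                    {base: 12330}
  cost_oc_diagnosis:           {base: 21800}
  cost_oc_annual_y1_2:         {base: 7300}
  cost_oc_annual_y3_5:         {base: 7010}
  cost_oc_terminal:            {base: 52697}
  cost_bc_diagnosis_general:   {base: 33155}
  cost_bc_diagnosis_carrier:   {base: 33155}
  cost_bc_annual_general:      {base: 1414}
  cost_bc_annual_carrier:      {base: 1284}
  cost_bc_terminal:            {base: 43638}
  cost_hrt_annual:             {base: 680}
  cost_mammography:            {base: 144}
  cost_mri:                    {base: 130}
  cost_chd_fatal:              {base: 4839}
  cost_chd_annual:             {base: 175}
  cost_chemoprevention_annual: {base: 293}
  cost_vus_reclassification:   {base: 0, rule: fixed, source: assumption}

utilities:
  utility_rrm:                 {base: 0.88, sd: 0.22}
  utility_rrso:                {base: 0.95, sd: 0.10}
  utility_bc_early:            {base: 0.71}
  utility_bc_advanced:         {base: 0.65}
  utility_bc_recurrent:        {base: 0.45}
  utility_bc_remission:        {base: 0.81}
  utility_bc_terminal:         {base: 0.16}
  utility_oc_early:            {base: 0.81}
  utility_oc_advanced:         {base: 0.55}
  utility_oc_recurrent:        {base: 0.61}
  utility_oc_remission:        {base: 0.83}
  utility_oc_terminal:         {base: 0.16}
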