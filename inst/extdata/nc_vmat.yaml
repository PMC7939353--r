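schema_version: 1
config:
  start_age: 65.0
  horizon_cycles: 15
  cycle_length: 1.0
  discount_rate: 0.03
  reference_strategy: SOC
  wtp_thresholds:
  - 50000.0
  - 100000.0
  half_cycle_correction: no
  reward_timing: end
  recurrence_progresses: yes
  recurrence_bc_death: yes
  beta_range_semantics: ci95
technique:
  name: NC_VMAT
  upfront_cost: 17438.0
  side_effect_probs:
    cardiac:
      base: 0.0105
      low: 0.0065
      high: 0.0151
      sd: .na.real
      family: beta
    cl_breast:
      base: 0.0027
      low: 0.0017
      high: 0.0078
      sd: .na.real
      family: beta
    lung:
      base: 0.0018
      low: 0.0013
      high: 0.0025
      sd: .na.real
      family: beta
states:
- name: NED
  is_initial: yes
  utility:
  - start: 0
    end: 5
    value: 0.734
  - start: 5
    end: 10
    value: 0.716
  - start: 10
    end: 15
    value: 0.675
  entry_cost: 0.0
  annual_cost: 0.0
  is_death: no
  death_category: none
  earliest_entry_cycle: 0
  utility_unc: ~
  entry_cost_unc: ~
- name: Recurrence
  is_initial: no
  utility:
  - start: 0
    end: 5
    value: 0.66
  - start: 5
    end: 10
    value: 0.65
  - start: 10
    end: 15
    value: 0.61
  entry_cost: 20879.0
  annual_cost: 0.0
  is_death: no
  death_category: none
  earliest_entry_cycle: 0
  utility_unc: ~
  entry_cost_unc: ~
- name: Metastasis
  is_initial: no
  utility:
  - start: 0
    end: 5
    value: 0.44
  - start: 5
    end: 10
    value: 0.43
  - start: 10
    end: 15
    value: 0.41
  entry_cost: 13627.0
  annual_cost: 0.0
  is_death: no
  death_category: none
  earliest_entry_cycle: 0
  utility_unc: ~
  entry_cost_unc: ~
- name: Cardiac
  is_initial: no
  utility:
  - start: 0
    end: 15
    value: 0.57
  entry_cost: 11570.0
  annual_cost: 0.0
  is_death: no
  death_category: none
  earliest_entry_cycle: 10
  utility_unc:
    base: 0.57
    low: 0.54
    high: 0.61
    sd: .na.real
    family: beta
  entry_cost_unc:
    base: 11570.0
    low: .na.real
    high: .na.real
    sd: 3405.0
    family: gamma
- name: CLBreast
  is_initial: no
  utility:
  - start: 0
    end: 15
    value: 0.54
  entry_cost: 14494.0
  annual_cost: 0.0
  is_death: no
  death_category: none
  earliest_entry_cycle: 5
  utility_unc:
    base: 0.54
    low: 0.48
    high: 0.55
    sd: .na.real
    family: beta
  entry_cost_unc:
    base: 14494.0
    low: .na.real
    high: .na.real
    sd: 1199.0
    family: gamma
- name: Lung
  is_initial: no
  utility:
  - start: 0
    end: 15
    value: 0.5
  entry_cost: 20577.0
  annual_cost: 0.0
  is_death: no
  death_category: none
  earliest_entry_cycle: 10
  utility_unc:
    base: 0.5
    low: 0.39
    high: 0.56
    sd: .na.real
    family: beta
  entry_cost_unc:
    base: 20577.0
    low: .na.real
    high: .na.real
    sd: 2740.0
    family: gamma
- name: Death_BC
  is_initial: no
  utility: ~
  entry_cost: 0.0
  annual_cost: 0.0
  is_death: yes
  death_category: breast_cancer
  earliest_entry_cycle: 0
  utility_unc: ~
  entry_cost_unc: ~
- name: Death_Tox
  is_initial: no
  utility: ~
  entry_cost: 0.0
  annual_cost: 0.0
  is_death: yes
  death_category: toxicity
  earliest_entry_cycle: 0
  utility_unc: ~
  entry_cost_unc: ~
- name: Death_Other
  is_initial: no
  utility: ~
  entry_cost: 0.0
  annual_cost: 0.0
  is_death: yes
  death_category: other_cause
  earliest_entry_cycle: 0
  utility_unc: ~
  entry_cost_unc: ~
transitions:
- from: NED
  to: Recurrence
  id: recurrence
  interpretation: annual
  ambiguous: yes
  prob:
  - start: 0
    end: 5
    value: 0.0146
  - start: 5
    end: 10
    value: 0.0054
  - start: 10
    end: 15
    value: 0.0006
  param_ref: ~
- from: NED
  to: Metastasis
  id: metastasis
  interpretation: period_cumulative
  ambiguous: yes
  prob:
  - start: 0
    end: 5
    value: 0.1225
  - start: 5
    end: 10
    value: 0.0775
  - start: 10
    end: 15
    value: 0.0775
  param_ref: ~
- from: Recurrence
  to: Metastasis
  id: progression
  interpretation: period_cumulative
  ambiguous: yes
  prob:
  - start: 0
    end: 5
    value: 0.1225
  - start: 5
    end: 10
    value: 0.0775
  - start: 10
    end: 15
    value: 0.0775
  param_ref: ~
- from: Metastasis
  to: Death_BC
  id: met_death
  interpretation: annual
  ambiguous: yes
  prob:
  - start: 0
    end: 5
    value: 0.232
  - start: 5
    end: 15
    value: 0.14
  param_ref: ~
- from: Recurrence
  to: Death_BC
  id: met_death
  interpretation: annual
  ambiguous: yes
  prob:
  - start: 0
    end: 5
    value: 0.232
  - start: 5
    end: 15
    value: 0.14
  param_ref: ~
- from: Cardiac
  to: Death_Tox
  id: cardiac_death
  interpretation: annual
  ambiguous: no
  prob:
  - start: 10
    end: 15
    value: 0.0053
  param_ref: ~
- from: CLBreast
  to: Death_Tox
  id: cl_breast_death
  interpretation: annual
  ambiguous: no
  prob:
  - start: 5
    end: 15
    value: 0.0212
  param_ref: ~
- from: Lung
  to: Death_Tox
  id: lung_death
  interpretation: annual
  ambiguous: no
  prob:
  - start: 10
    end: 15
    value: 0.00078
  param_ref: ~
- from: NED
  to: Cardiac
  id: cardiac_onset
  interpretation: annual
  ambiguous: no
  prob: ~
  param_ref: cardiac
- from: NED
  to: CLBreast
  id: cl_breast_onset
  interpretation: annual
  ambiguous: no
  prob: ~
  param_ref: cl_breast
- from: NED
  to: Lung
  id: lung_onset
  interpretation: annual
  ambiguous: no
  prob: ~
  param_ref: lung
other_cause_mortality:
- start: 0
  end: 5
  value: 0.0146
- start: 5
  end: 10
  value: 0.0171
- start: 10
  end: 15
  value: 0.0353
meta:
  schema_version: 1
  description: WBRT cost-effectiveness fixture, strategy NC_VMAT
  interpretations:
    recurrence: annual
    metastasis: period_cumulative
    met_death: annual
    progression: period_cumulative
  notes: IMRT cl_breast printed range 0.71-0.71 is degenerate; low bound 0.12 substituted
    from the HybridIMRT-like asymmetric spread, high bound 0.71 kept as printed.

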