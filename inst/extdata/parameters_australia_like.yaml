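schema_version: 1
simulation:
  entry_age: 15.0
  max_age: 85.0
demographics:
  prop_female: 0.5
  birth_year_min: 1935.0
  birth_year_max: 1995.0
baseline_incidence:
  age_breaks:
  - 15.0
  - 20.0
  - 25.0
  - 30.0
  - 35.0
  - 40.0
  - 45.0
  - 50.0
  - 55.0
  - 60.0
  - 65.0
  - 70.0
  - 75.0
  - 80.0
  - 85.0
  male:
  - 0.0001
  - 0.00015
  - 0.00025
  - 0.0004
  - 0.0006
  - 0.0009
  - 0.0013
  - 0.0018
  - 0.0024
  - 0.003
  - 0.0036
  - 0.0042
  - 0.0047
  - 0.005
  female:
  - 0.00015
  - 0.0002
  - 0.0003
  - 0.00045
  - 0.0006
  - 0.00075
  - 0.0009
  - 0.0011
  - 0.0013
  - 0.0015
  - 0.0017
  - 0.0019
  - 0.0021
  - 0.0023
  scale: 1.0
cohort_effect:
  decline_start: 1972.0
  decline_end: 1992.0
  floor: 0.65
risk_groups:
- label: low
  fraction: 0.25
  relative_risk: 0.5
  uptake_multiplier: 0.7
- label: average
  fraction: 0.55
  relative_risk: 1.0
  uptake_multiplier: 1.0
- label: high
  fraction: 0.2
  relative_risk: 2.75
  uptake_multiplier: 1.4
histology_mix:
  age_breaks:
  - 15.0
  - 40.0
  - 60.0
  - 85.0
  codes:
  - superficial_spreading
  - lentigo_maligna
  - nodular
  - other
  props:
  - - 0.62
    - 0.03
    - 0.1
    - 0.25
  - - 0.55
    - 0.1
    - 0.12
    - 0.23
  - - 0.42
    - 0.22
    - 0.14
    - 0.22
stage_schedules:
  superficial_spreading:
    thresholds:
      I: 1.0
      II: 3.0
      III: 5.0
      IV: 7.0
    breslow_cutpoints:
    - 1.8
    - 4.0
  lentigo_maligna:
    thresholds:
      I: 8.0
      II: 14.0
      III: 18.0
      IV: 20.0
    breslow_cutpoints:
    - 10.0
    - 16.0
  nodular:
    thresholds:
      I: 0.1
      II: 0.25
      III: 0.4
      IV: 0.5
    breslow_cutpoints:
    - 0.15
    - 0.3
  other:
    thresholds:
      I: 1.5
      II: 4.0
      III: 6.5
      IV: 9.0
    breslow_cutpoints:
    - 2.5
    - 5.5
body_sites:
  codes:
  - C44.0
  - C44.1
  - C44.2
  - C44.3
  - C44.4
  - C44.5
  - C44.6
  - C44.7
  - C44.8
  - C44.9
  probs:
  - 0.02
  - 0.03
  - 0.08
  - 0.12
  - 0.05
  - 0.25
  - 0.2
  - 0.18
  - 0.04
  - 0.03
  visible:
  - yes
  - yes
  - yes
  - yes
  - no
  - yes
  - yes
  - yes
  - no
  - no
detection:
  curves:
    superficial_spreading:
      p0: 0.25
      pmax: 0.8
      rate: 0.8
    lentigo_maligna:
      p0: 0.12
      pmax: 0.65
      rate: 0.15
    nodular:
      p0: 0.35
      pmax: 0.35
      rate: 0.0
    other:
      p0: 0.2
      pmax: 0.7
      rate: 0.5
  visibility_less_factor: 0.8
  period:
    start_year: 1980.0
    end_year: 2010.0
    start_factor: 0.7
    end_factor: 1.0
  specificity:
    opportunistic_visit: 0.99
    routine_check: 0.985
    surveillance: 0.985
uptake_model:
  age_breaks:
  - 15.0
  - 30.0
  - 45.0
  - 60.0
  - 85.0
  rates:
  - 0.005
  - 0.02
  - 0.04
  - 0.05
  female_factor: 1.2
  calendar:
    start_year: 1980.0
    end_year: 2015.0
    start_factor: 0.15
    end_factor: 1.0
attendance:
  initial: 0.9
  decay_rate: 0.05
routine_interval: 1.0
visit_rates:
  age_breaks:
  - 15.0
  - 30.0
  - 45.0
  - 60.0
  - 85.0
  rates:
  - 0.12
  - 0.15
  - 0.2
  - 0.3
  female_factor: 1.15
  emergence_boost: 2.0
  boost_cap_years: 5.0
post_diagnosis_risk_multipliers:
- 6.0
- 7.5
- 9.0
- 10.5
subsequent_histology_concordance: 0.55
subsequent_histology_factor:
  superficial_spreading: 1.0
  lentigo_maligna: 1.0
  nodular: 1.0
  other: 1.0
survival:
  time_breaks:
  - 0.0
  - 1.0
  - 5.0
  hazards:
    in_situ:
      any:
      - 0.0
      - 0.0
      - 0.0
    I:
      le_1mm:
      - 0.001
      - 0.002
      - 0.001
      b1_4mm:
      - 0.01
      - 0.012
      - 0.006
      gt_4mm:
      - 0.02
      - 0.02
      - 0.01
    II:
      le_1mm:
      - 0.015
      - 0.02
      - 0.01
      b1_4mm:
      - 0.03
      - 0.035
      - 0.015
      gt_4mm:
      - 0.05
      - 0.05
      - 0.02
    III:
      any:
      - 0.08
      - 0.09
      - 0.04
    IV:
      any:
      - 0.5
      - 0.35
      - 0.12
surveillance:
  intensive_interval: 0.5
  standard_interval: 1.0
  intensive_stages:
  - III
  - IV
  intensive_risk_labels: high
  attendance_initial: 0.95
  attendance_decay: 0.04
  stage_attendance_factor:
    in_situ: 0.95
    I: 1.0
    II: 1.0
    III: 1.0
    IV: 1.0
  histology_attendance_factor:
    superficial_spreading: 1.0
    lentigo_maligna: 1.0
    nodular: 1.0
    other: 1.0
economics:
  discount_rate: 0.05
  wtp_threshold: 50000.0
  keratinocyte_adjunct_cost: 15.0
  tariff:
    check_cost:
      opportunistic_visit: 40.0
      routine_check: 45.0
      organised_screen: 60.0
      surveillance: 80.0
    diagnostic_excision: 320.0
    false_positive_workup: 180.0
    treatment_initial:
      in_situ: 600.0
      I: 1800.0
      II: 4500.0
      III: 32000.0
      IV: 110000.0
    treatment_continuing:
      in_situ: 0.0
      I: 120.0
      II: 350.0
      III: 2500.0
      IV: 18000.0
    continuing_years: 5.0
    program_per_invitee: 5.0
    program_fixed_annual: 0.0
  utilities:
    well: 1.0
    in_situ: 0.97
    I: 0.95
    II: 0.92
    III: 0.85
    IV: 0.7
life_table:
  age_breaks:
  - 15.0
  - 20.0
  - 25.0
  - 30.0
  - 35.0
  - 40.0
  - 45.0
  - 50.0
  - 55.0
  - 60.0
  - 65.0
  - 70.0
  - 75.0
  - 80.0
  - 85.0
  male:
  - 0.0005
  - 0.0008
  - 0.0009
  - 0.001
  - 0.0013
  - 0.0018
  - 0.0025
  - 0.004
  - 0.006
  - 0.009
  - 0.014
  - 0.022
  - 0.036
  - 0.06
  female:
  - 0.0003
  - 0.0004
  - 0.0005
  - 0.0006
  - 0.0009
  - 0.0013
  - 0.0019
  - 0.003
  - 0.0045
  - 0.007
  - 0.011
  - 0.017
  - 0.028
  - 0.048
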