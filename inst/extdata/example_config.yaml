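# Example picost configuration. All blocks optional; omitted fields keep
# package defaults.
cost_parameters:
  per_day_components:
    procedures: 1000
    labor: 1500
    support_surface: 500
    nutrition: 1000
  device_cost: 77000
  cases_per_device: 12
  consumables_per_case: 3600
  es_staff_minutes_per_day: 15
  wage_per_minute: 50
healing_time_table:
  superficial: [15, 33, 140]   # DESIGN-R <=9, 10-18, >=19
  deep: [26, 63, 259]
generator_spec:
  n_patients: 12
  target_mean_red_es: 0.179
  target_mean_red_pl: 0.051
  sd_red_es: 0.15
  sd_red_pl: 0.08
  cor_red: 0.5
  seed: 1
  strata:
    - {category: "10-18", depth: deep, count: 5}
    - {category: ">=19", depth: deep, count: 7}
scenarios:
  - {name: base_case}
  - {name: value_8000, per_day_value: 8000}
  - {name: ratio_plus20, ratio_multiplier: 1.2}
  - {name: diminishing, translation_mode: diminishing, kappa: 0.5}
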