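# Base-case configuration: every value here restates the package defaults,
# so an empty file (or no file) produces the identical model.
parameters:
  prevalence_asd: 0.15
  sens_mri_6: 0.82
  sens_mri_12: 0.88
  spec_mri_6: 1.00
  spec_mri_12: 0.95
  p_early_intervention: 0.62
  p_id_without_ei: 0.37
  rr_id_with_ei: 0.61
  hr_asd: 2.18
  hr_asd_id: 5.78
  qol_asd: 0.68
  qol_asd_id: 0.46
  cost_mri: 1814
  cost_ei: 148367
  discount_rate: 0.03

cost_schedule:
  outcome_class: [asd_only, asd_only, asd_only, asd_id, asd_id, asd_id, non_asd]
  age_from:     [6, 18, 22, 6, 18, 22, 6]
  age_to:       [17, 21, .inf, 17, 21, .inf, .inf]
  annual_cost:  [58526, 69889, 54154, 95983, 127718, 96247, 0]

run:
  perspectives: [societal, health_care, educational]
  wtp: [50000, 100000]
  psa_n: 10000
  seed: 20180101
  baseline: status_quo
  comparator: test_treat_6
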