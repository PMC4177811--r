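# Default synthetic-cohort configuration: an elderly (60+) Norwegian-style
# population screening cohort. Values mirror the package defaults in
# cohort_config(); the file exists so runs can be driven from an editable,
# versionable document.
"n": 2992
sex_fraction_female: 0.547
age:
  female: {mean: 69.3, sd: 6.3}
  male: {mean: 69.7, sd: 5.7}
age_range: [60, 90]
bmd:
  female: {mean: 0.83, sd: 0.12}
  male: {mean: 0.94, sd: 0.13}
bmd_age_slope: -0.003
weight:
  female: {mean: 69.1, sd: 11.8}
  male: {mean: 80.7, sd: 11.7}
weight_bmd_cor: 0.3
prior_fracture_probs:
  female: [0.742, 0.155, 0.070, 0.033]
  male: [0.900, 0.074, 0.020, 0.006]
falls_probs:
  female: [0.691, 0.296, 0.013]
  male: [0.684, 0.299, 0.017]
mortality_rate: 0.02
mortality_age_slope: 0
admin_censor_years: 8.2
noise_sd_weight_channel: 0.6
seed: 42
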