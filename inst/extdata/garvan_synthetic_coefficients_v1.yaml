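# Synthetic reconstruction of the Garvan absolute fracture-risk equations.
#
# The original equations are distributed as a supplement to the model's
# publications and are not redistributable here; this document is a
# SYNTHETIC parameter set that reproduces the published model STRUCTURE:
#   - sex-specific Cox proportional-hazards linear predictor over age,
#     femoral-neck BMD T-score (or body weight), prior low-trauma
#     fractures since age 50 (categories 0, 1, 2, 3+) and falls in the
#     past 12 months (categories 0, 1, 2+);
#   - absolute risk at horizon t in {5, 10} years:
#       risk = 1 - s0[t] ^ exp(lp - lp_center)
#     where s0[t] is the baseline survival at the centring profile.
# Hazard-ratio magnitudes follow the osteoporosis literature (risk roughly
# doubles per prior fracture; 1.5-2.6x per SD lower femoral-neck BMD, the
# larger gradient for hip fracture; hip risk rises ~3x per decade of age).
# Baseline survival constants are anchored so that a profile at the
# predictor means of an elderly Norwegian screening cohort lands near the
# centre of the predicted-risk distributions such cohorts report.
#
# Edit with care: every block must keep all keys; the loader validates
# completeness and refuses partial documents.
version: "1.0-synthetic"
source: >
  Synthetic coefficient set in the functional form of the Garvan fracture
  risk nomograms (Dubbo Osteoporosis Epidemiology Study models); not a
  transcription of the published coefficients.
model_form: "risk(t) = 1 - s0[t]^exp(lp - lp_center)"
# Young-adult femoral-neck reference (Lunar densitometer) used to convert
# between areal BMD in g/cm^2 and T-score: t = (bmd - mean) / sd.
tscore_reference:
  female: {mean: 1.005, sd: 0.120}
  male: {mean: 1.058, sd: 0.130}
# Top categories: prior_fracture scores are for counts 0,1,2,3+ and falls
# scores for 0,1,2+; higher observed counts are clamped to the top score.
blocks:
  any_female_bmd:
    outcome: any
    sex: female
    variant: bmd
    age: 0.055
    tscore: -0.45
    prior_fracture: [0.0, 0.60, 0.95, 1.25]
    falls: [0.0, 0.30, 0.55]
    lp_center: 4.5090
    s0: {"5": 0.928, "10": 0.845}
  hip_female_bmd:
    outcome: hip
    sex: female
    variant: bmd
    age: 0.105
    tscore: -0.95
    prior_fracture: [0.0, 0.65, 1.05, 1.40]
    falls: [0.0, 0.45, 0.80]
    lp_center: 8.7490
    s0: {"5": 0.989, "10": 0.977}
  any_male_bmd:
    outcome: any
    sex: male
    variant: bmd
    age: 0.060
    tscore: -0.50
    prior_fracture: [0.0, 0.70, 1.10, 1.45]
    falls: [0.0, 0.35, 0.60]
    lp_center: 4.6570
    s0: {"5": 0.961, "10": 0.918}
  hip_male_bmd:
    outcome: hip
    sex: male
    variant: bmd
    age: 0.115
    tscore: -0.90
    prior_fracture: [0.0, 0.75, 1.20, 1.55]
    falls: [0.0, 0.50, 0.85]
    lp_center: 8.8705
    s0: {"5": 0.9957, "10": 0.9900}
  any_female_weight:
    outcome: any
    sex: female
    variant: weight
    age: 0.050
    weight: -0.015
    prior_fracture: [0.0, 0.65, 1.00, 1.30]
    falls: [0.0, 0.35, 0.60]
    lp_center: 2.4285
    s0: {"5": 0.926, "10": 0.842}
  hip_female_weight:
    outcome: hip
    sex: female
    variant: weight
    age: 0.110
    weight: -0.035
    prior_fracture: [0.0, 0.70, 1.10, 1.45]
    falls: [0.0, 0.50, 0.85]
    lp_center: 5.2045
    s0: {"5": 0.988, "10": 0.976}
  any_male_weight:
    outcome: any
    sex: male
    variant: weight
    age: 0.055
    weight: -0.012
    prior_fracture: [0.0, 0.75, 1.15, 1.50]
    falls: [0.0, 0.40, 0.65]
    lp_center: 2.8651
    s0: {"5": 0.960, "10": 0.916}
  hip_male_weight:
    outcome: hip
    sex: male
    variant: weight
    age: 0.120
    weight: -0.030
    prior_fracture: [0.0, 0.80, 1.25, 1.60]
    falls: [0.0, 0.55, 0.90]
    lp_center: 5.9430
    s0: {"5": 0.9955, "10": 0.9895}
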