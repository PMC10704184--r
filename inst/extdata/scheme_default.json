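{
  "variables": {
    "age_group": ["[0, 18)", "[18, 30)", "[30, 40)", "[40, 50)", "[50, 65)", "[65, 75)", "[75, 85)", "[85, 140)", "Not reported"],
    "race": ["American Indian or Alaska Native", "Asian", "Black or African American", "Native Hawaiian or other Pacific Islander", "White", "Not reported", "Other"],
    "sex_at_birth": ["Female", "Male", "Other", "Not reported"],
    "ethnicity": ["Hispanic or Latino", "Not Hispanic or Latino", "Not reported"],
    "covid_status": ["No", "Not reported", "Yes"],
    "modality": ["CR", "CT", "DX", "MR"]
  },
  "age_bins": [0, 18, 30, 40, 50, 65, 75, 85, 140],
  "missing_label": "Not reported",
  "open_fraction": 0.8,
  "age_variable": "age_group",
  "modality_variable": "modality"
}
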