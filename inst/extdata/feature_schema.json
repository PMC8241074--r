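{
  "version": 1,
  "encoded_widths": {"general": 10, "visit": 21, "medication": 18},
  "general": [
    {"name": "age", "kind": "numeric"},
    {"name": "minimal_disease_activity", "kind": "numeric", "missing_indicator": true},
    {"name": "disease_duration", "kind": "numeric", "missing_indicator": true},
    {"name": "gender", "kind": "categorical", "levels": ["female", "male"], "encode": "binary_female"},
    {"name": "rf_status", "kind": "categorical", "levels": ["positive", "negative"]},
    {"name": "anti_ccp", "kind": "categorical", "levels": ["positive", "negative"]}
  ],
  "visit": [
    {"name": "swollen_count", "kind": "numeric"},
    {"name": "painful_count", "kind": "numeric"},
    {"name": "bsr", "kind": "numeric", "missing_indicator": true},
    {"name": "das28_bsr", "kind": "numeric", "missing_indicator": true},
    {"name": "pain", "kind": "numeric"},
    {"name": "radai", "kind": "numeric"},
    {"name": "haq", "kind": "numeric"},
    {"name": "weight", "kind": "numeric"},
    {"name": "height", "kind": "numeric"},
    {"name": "morning_stiffness", "kind": "categorical",
     "levels": ["none", "lt_half_hour", "half_to_one_hour", "gt_four_hours",
                "twelve_hours", "twenty_four_hours", "all_day"]},
    {"name": "smoker", "kind": "categorical", "levels": ["never", "current", "former"]},
    {"name": "crp", "kind": "numeric", "optional": true},
    {"name": "euroqol", "kind": "numeric", "optional": true}
  ],
  "medication": [
    {"name": "drug", "kind": "categorical",
     "levels": ["methotrexate", "prednisone", "adalimumab", "etanercept", "tocilizumab",
                "abatacept", "rituximab", "golimumab", "other"]},
    {"name": "drug_type", "kind": "categorical",
     "levels": ["csDMARD", "prednisone", "biologic", "other"]},
    {"name": "prednisone_dose_stratum", "kind": "categorical",
     "levels": ["none", "lt10", "10to15", "gt15"]},
    {"name": "time_since_adjustment", "kind": "numeric", "derived": true,
     "scale": {"min": 0, "max": 60}}
  ]
}
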