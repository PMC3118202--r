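{
  "design": {
    "n_per_arm": 100,
    "n_lesions": 10,
    "followup_days": 1095,
    "censoring": {"shape": 2.1399, "scale": 5.76e-7},
    "hazard_ratio": 0.7692307692307693,
    "lesion_process": "sequential"
  },
  "scenario": {
    "name": "scenario1",
    "components": [
      {"proportion": 1.0, "shape": 1.1452, "scale": 0.00141}
    ]
  }
}
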