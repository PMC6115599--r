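{
  "flavor_accuracy": ["flavor", "juice", "vape", "taste", "aftertaste"],
  "value": ["price", "value", "quality"],
  "cloud_production": ["vapor production", "vapor", "cloud production"],
  "throat_hit": ["throat", "hit", "throat hit"]
}
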