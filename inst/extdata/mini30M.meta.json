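{
  "age_years": 30,
  "sex": "M",
  "height_cm": 176,
  "weight_kg": 73,
  "id": "mini30M",
  "site_name_map": {
    "Femora, proximal head": 1,
    "Os coxae": 2,
    "Sacrum": 3,
    "Lumbar vertebrae": 4,
    "Ribs": 5,
    "Craniofacial bones": 6
  }
}
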