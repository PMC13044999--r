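{
  "name": "therapy",
  "fields": [
    {"name": "case_pseudonym", "type": "character", "required": true},
    {"name": "device_type", "type": "character", "required": true},
    {"name": "start_ts", "type": "timestamp", "required": true},
    {"name": "end_ts", "type": "timestamp", "required": false},
    {"name": "end_inferred", "type": "logical", "required": true},
    {"name": "ongoing", "type": "logical", "required": true},
    {"name": "n_source_records", "type": "integer", "required": true}
  ],
  "plausibility": [
    {"field": "device_type",
     "allowed": ["ECMO", "dialysis", "microaxial_pump", "IABP"]},
    {"field": "n_source_records", "min": 1, "max": 1000000}
  ],
  "cross_field": [
    {"name": "start<=end", "rule": "le", "left": "start_ts", "right": "end_ts"}
  ]
}
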