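{
  "name": "observations",
  "fields": [
    {"name": "case_pseudonym", "type": "character", "required": true},
    {"name": "variable_id", "type": "character", "required": true},
    {"name": "value", "type": "numeric", "required": true},
    {"name": "unit", "type": "character", "required": true},
    {"name": "ts", "type": "timestamp", "required": true},
    {"name": "lower", "type": "numeric", "required": false},
    {"name": "upper", "type": "numeric", "required": false}
  ],
  "plausibility": [],
  "cross_field": [
    {"name": "value_in_catalog_bounds", "rule": "between",
     "field": "value", "low": "lower", "high": "upper"}
  ]
}
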