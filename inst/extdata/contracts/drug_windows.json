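{
  "name": "drug_windows",
  "fields": [
    {"name": "case_pseudonym", "type": "character", "required": true},
    {"name": "ingredient", "type": "character", "required": true},
    {"name": "unit", "type": "character", "required": true},
    {"name": "total", "type": "numeric", "required": true},
    {"name": "window_start", "type": "timestamp", "required": true},
    {"name": "window_end", "type": "timestamp", "required": true}
  ],
  "plausibility": [
    {"field": "total", "min": 0, "max": 1000000},
    {"field": "unit", "allowed": ["mg", "U"]}
  ],
  "cross_field": [
    {"name": "window_start<=window_end", "rule": "le",
     "left": "window_start", "right": "window_end"}
  ]
}
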