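{
  "name": "or_times",
  "fields": [
    {"name": "case_pseudonym", "type": "character", "required": true},
    {"name": "or_start", "type": "timestamp", "required": true},
    {"name": "or_end", "type": "timestamp", "required": true}
  ],
  "plausibility": [],
  "cross_field": [
    {"name": "or_start<=or_end", "rule": "le", "left": "or_start", "right": "or_end"}
  ]
}
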