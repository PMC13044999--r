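{
  "name": "drugs",
  "fields": [
    {"name": "case_pseudonym", "type": "character", "required": true},
    {"name": "ingredient", "type": "character", "required": true},
    {"name": "kind", "type": "character", "required": true},
    {"name": "value", "type": "numeric", "required": true},
    {"name": "unit", "type": "character", "required": true},
    {"name": "start_ts", "type": "timestamp", "required": true},
    {"name": "end_ts", "type": "timestamp", "required": false}
  ],
  "plausibility": [
    {"field": "value", "min": 0, "max": 10000},
    {"field": "kind", "allowed": ["bolus", "infusion"]},
    {"field": "unit", "allowed": ["mg", "U", "mg/h", "U/h"]}
  ],
  "cross_field": [
    {"name": "start<=end", "rule": "le", "left": "start_ts", "right": "end_ts"}
  ]
}
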