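{
  "icu_datamanager": ["*"],
  "study_nurse": ["demographics"],
  "perioperative_researcher": ["demographics", "periop_study"]
}
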