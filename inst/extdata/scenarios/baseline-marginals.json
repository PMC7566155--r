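{
  "name": "baseline-marginals",
  "description": "Unconditioned bounds on the place of death: the model's view of the whole cohort before any patient-specific information.",
  "queries": [
    {"label": "pod_home", "target": "place_of_death=home"},
    {"label": "pod_hospital", "target": "place_of_death=hospital"},
    {"label": "pod_nursing_home", "target": "place_of_death=nursing_home"}
  ]
}
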