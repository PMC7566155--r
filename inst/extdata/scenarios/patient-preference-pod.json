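{
  "name": "patient-preference-pod",
  "description": "The patient's own preference has a much weaker influence on the place of death than the family's.",
  "queries": [
    {"label": "pod_home_given_pp_home", "target": "place_of_death=home",
     "evidence": {"patient_preference": "home"}},
    {"label": "impact_patient_preference", "target": "place_of_death=home",
     "impact": {"variable": "patient_preference", "mode": "do"},
     "reported": "14% impact of the patient's preference"}
  ]
}
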