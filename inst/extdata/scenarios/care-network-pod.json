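{
  "name": "care-network-pod",
  "description": "Effect of specialist palliative home care within a congruent home preference: both patient and family prefer home.",
  "queries": [
    {"label": "pod_home_congruent_with_phc", "target": "place_of_death=home",
     "evidence": {"family_preference": "home", "patient_preference": "home"},
     "do": {"palliative_home_care": "yes"},
     "reported": "76-83% home death with full home-care network"},
    {"label": "pod_home_congruent_no_phc", "target": "place_of_death=home",
     "evidence": {"family_preference": "home", "patient_preference": "home"},
     "do": {"palliative_home_care": "no"},
     "reported": "home death decreases by 24% without specialist palliative home care"},
    {"label": "impact_phc_congruent", "target": "place_of_death=home",
     "evidence": {"family_preference": "home", "patient_preference": "home"},
     "impact": {"variable": "palliative_home_care", "mode": "do"}}
  ]
}
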