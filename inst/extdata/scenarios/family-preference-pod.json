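{
  "name": "family-preference-pod",
  "description": "The family's preference for the last place of care and its effect on the place of death.",
  "queries": [
    {"label": "pod_home_marginal", "target": "place_of_death=home"},
    {"label": "pod_home_given_fp_home", "target": "place_of_death=home",
     "evidence": {"family_preference": "home"},
     "reported": "53-70% home death when the family prefers home"},
    {"label": "pod_hospital_given_fp_hospital", "target": "place_of_death=hospital",
     "evidence": {"family_preference": "hospital"},
     "reported": "59-87% hospital death when the family prefers hospital"},
    {"label": "pod_home_do_fp_home", "target": "place_of_death=home",
     "do": {"family_preference": "home"}},
    {"label": "impact_family_preference", "target": "place_of_death=home",
     "impact": {"variable": "family_preference", "mode": "do"},
     "reported": "51% overall impact of the family's preference"}
  ]
}
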