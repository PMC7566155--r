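{
  "name": "family-conditions-preference",
  "description": "Suitable family conditions for home care drive the family's preference for a home death.",
  "queries": [
    {"label": "fp_home_do_suitable", "target": "family_preference=home",
     "do": {"family_conditions": "suitable"}},
    {"label": "fp_home_do_unsuitable", "target": "family_preference=home",
     "do": {"family_conditions": "unsuitable"}},
    {"label": "impact_conditions_on_fp", "target": "family_preference=home",
     "impact": {"variable": "family_conditions", "mode": "do"},
     "reported": "35% more suitable conditions under open communication and symptom control"},
    {"label": "suitable_given_no_family_member", "target": "family_conditions=suitable",
     "evidence": {"family_member_available": "no"},
     "reported": "suitability drops to 20-40% without an available family member"}
  ]
}
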